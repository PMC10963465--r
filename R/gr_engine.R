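#' Growth-and-remodeling parameters
#'
#' One point of the G&R parameter space: the stress gain, the three
#' inflammation gains, the inflammation shape parameters and the collagen
#' characteristic time.
#'
#' @param k_sigma Stress-mediated collagen production gain (dimensionless).
#' @param k_gplus_c Inflammatory collagen production gain (dimensionless).
#' @param k_gminus_c Inflammatory collagen degradation gain (dimensionless).
#' @param k_gminus_e Inflammatory elastin degradation gain, per 3-day growth
#'   step (the kinetic law carries the 1/3 per-step to per-day conversion).
#' @param delta Inflammation shape parameter, 1/day.
#' @param beta Inflammation shape parameter (> 1); transient patterns only.
#' @param T_c Characteristic time of collagen turnover, days (101).
#' @return An object of class `growth_parameters`.
#' @export
growth_parameters <- function(k_sigma, k_gplus_c, k_gminus_c, k_gminus_e,
                              delta, beta = NULL, T_c = 101) {
  vals <- c(k_sigma, k_gplus_c, k_gminus_c, k_gminus_e, delta, T_c)
  if (!all(is.finite(vals)) || any(vals < 0)) {
    stop("growth_parameters: gains, delta and T_c must be finite and >= 0",
         call. = FALSE)
  }
  if (T_c <= 0 || delta <= 0) {
    stop("growth_parameters: delta and T_c must be > 0", call. = FALSE)
  }
  if (!is.null(beta) && (!is.finite(beta) || beta <= 1)) {
    stop("growth_parameters: beta must be > 1 when supplied", call. = FALSE)
  }
  structure(list(k_sigma = k_sigma, k_gplus_c = k_gplus_c,
                 k_gminus_c = k_gminus_c, k_gminus_e = k_gminus_e,
                 delta = delta, beta = beta, T_c = T_c),
            class = "growth_parameters")
}

#' Constituent turnover rates
#'
#' Collagen production responds to the inflammatory burden and to the
#' deviation of the fiber stress from its homeostatic value,
#' \deqn{\dot\rho_+^{c,f} = \frac{\rho^{c,f}}{T^c}
#'   \left(1 + k_{\Gamma+}^c \Gamma + k_\sigma^c
#'   \frac{\sigma^{c,f} - \sigma_h^{c,f}}{\sigma_h^{c,f}}\right)_{\ge 0},}
#' floored at zero (production cannot be negative); degradation is
#' \deqn{\dot\rho_-^{c,f} = -\frac{\rho^{c,f}}{T^c}(1 + k_{\Gamma-}^c \Gamma).}
#' Elastin never regrows and degrades only under inflammation,
#' \deqn{\dot\rho_-^e = -\tfrac13 \rho^e\, k_{\Gamma-}^e\, \Gamma,}
#' the 1/3 converting the per-step gain (one growth step = 3 days) to per
#' day. With `Gamma = 0` production and degradation cancel exactly and the
#' homeostatic composition is a fixed point.
#'
#' @param rho_cf Collagen density of one fiber family (fraction of the
#'   initial configuration).
#' @param sigma_cf Current fiber Cauchy stress, MPa.
#' @param sigma_h Homeostatic fiber Cauchy stress, MPa (> 0; when 0, the
#'   stress-mediated term is dropped).
#' @param Gamma Inflammatory burden in \[0, 1\].
#' @param params A [growth_parameters()].
#' @return Rate in density fraction per day.
#' @export
collagen_production_rate <- function(rho_cf, sigma_cf, sigma_h, Gamma, params) {
  stopifnot(all(rho_cf >= 0))
  dev <- if (sigma_h > 0) (sigma_cf - sigma_h) / sigma_h else 0
  bracket <- 1 + params$k_gplus_c * Gamma + params$k_sigma * dev
  rho_cf / params$T_c * pmax(bracket, 0)
}

#' @rdname collagen_production_rate
#' @export
collagen_degradation_rate <- function(rho_cf, Gamma, params) {
  -rho_cf / params$T_c * (1 + params$k_gminus_c * Gamma)
}

#' @rdname collagen_production_rate
#' @param rho_e Elastin density (fraction of the initial configuration).
#' @export
elastin_degradation_rate <- function(rho_e, Gamma, params) {
  stopifnot(all(rho_e >= 0))
  -(1 / 3) * rho_e * params$k_gminus_e * Gamma
}

#' Growth tensor
#'
#' Inelastic volume change from net mass change, acting along the unit
#' growth direction only:
#' \deqn{F_g = \frac{\rho^{tot}(s)}{\rho^{tot}(0)}\, a_g \otimes a_g +
#'   (I - a_g \otimes a_g).}
#' Growth is radial; det F_g equals the density ratio.
#'
#' @param rho_tot_now,rho_tot_init Current and initial total density.
#' @param a_g Unit growth direction (default radial, (theta, z, r) ordering).
#' @return 3x3 growth tensor.
#' @export
growth_tensor <- function(rho_tot_now, rho_tot_init, a_g = c(0, 0, 1)) {
  if (rho_tot_init <= 0) {
    stop("growth_tensor: initial density must be > 0", call. = FALSE)
  }
  ratio <- rho_tot_now / rho_tot_init
  if (!is.finite(ratio) || ratio <= 0) {
    stop("growth_tensor: density ratio must be > 0 (failure record)",
         call. = FALSE)
  }
  a <- a_g / sqrt(sum(a_g^2))
  A <- a %*% t(a)
  ratio * A + (diag(3) - A)
}

#' Collagen remodeling tensor
#'
#' Volume-preserving inelastic stretch along the mean fiber direction:
#' \deqn{F_r^c = \lambda_r M^f \otimes M^f +
#'   \lambda_r^{-1/2} (I - M^f \otimes M^f),} with det F_r = 1 exactly.
#'
#' @param lambda_r Remodeling stretch (> 0).
#' @param M_f Unit mean fiber direction.
#' @return 3x3 remodeling tensor.
#' @export
remodeling_tensor <- function(lambda_r, M_f) {
  if (lambda_r <= 0) stop("remodeling_tensor: lambda_r must be > 0", call. = FALSE)
  m <- M_f / sqrt(sum(M_f^2))
  A <- m %*% t(m)
  lambda_r * A + (diag(3) - A) / sqrt(lambda_r)
}

#' Remodeling-stretch update by turnover-paced stress relaxation
#'
#' In the homogenized constrained mixture, collagen turnover re-sets the
#' fiber toward its preferred (homeostatic) stress at the turnover rate:
#' the fiber stress relaxes as
#' \deqn{\dot\sigma^{c,f} =
#'   \left(\dot\rho_+^{c,f}/\rho^{c,f} + 1/T^c\right)
#'   (\sigma_h^{c,f} - \sigma^{c,f}),}
#' which for a taut fiber is equivalent to the remodeling-stretch rate
#' equation \eqn{\dot\lambda_r\, \lambda_e\, \partial\sigma/\partial\lambda_e
#'   = \lambda_r (\dot\rho_+/\rho + 1/T^c)(\sigma - \sigma_h)} but remains
#' well defined at the slack limit. Each substep relaxes the stress exactly
#' (exponential update with the rate frozen over the substep) and inverts
#' the fiber law for the new elastic stretch; the remodeling stretch follows
#' from the fixed total fiber stretch. Stationary exactly at
#' \eqn{\sigma = \sigma_h}.
#'
#' @param lam_r Current remodeling stretch.
#' @param lam_fib_add Additional (macroscopic) fiber stretch relative to the
#'   in vivo reference, held fixed over the substep.
#' @param mat A [layer_material()].
#' @param turnover_rate \eqn{\dot\rho_+/\rho + 1/T^c}, per day.
#' @param dt Substep, days.
#' @param deposition_stretch Collagen deposition stretch (1.10).
#' @return List with `lam_r`, `lam_e`, `sigma_f` after the substep.
#' @export
update_remodeling_stretch <- function(lam_r, lam_fib_add, mat, turnover_rate,
                                      dt, deposition_stretch = 1.10) {
  sigma_h <- homeostatic_fiber_stress(mat, deposition_stretch)
  lam_e <- deposition_stretch * lam_fib_add / lam_r
  sigma <- fiber_cauchy_stress(lam_e, mat)
  if (sigma_h <= 0) {
    return(list(lam_r = lam_r, lam_e = lam_e, sigma_f = sigma))
  }
  sigma_new <- sigma_h + (sigma - sigma_h) * exp(-turnover_rate * dt)
  lam_e_new <- fiber_stress_inverse(sigma_new, mat)
  lam_r_new <- deposition_stretch * lam_fib_add / lam_e_new
  list(lam_r = lam_r_new, lam_e = lam_e_new,
       sigma_f = fiber_cauchy_stress(lam_e_new, mat))
}

# One forward-Euler kinetics substep of a material point with frozen
# macroscopic kinematics. point: list(rho_e, rho_c, lam_r); returns the
# updated point. Density integration is forward Euler (first order); the
# remodeling stretch uses the exact relaxation update above.
gr_point_substep <- function(point, mat, params, Gamma, h, lam_fib_add,
                             deposition_stretch = 1.10) {
  sigma_h <- homeostatic_fiber_stress(mat, deposition_stretch)
  lam_e <- deposition_stretch * lam_fib_add / point$lam_r
  sigma <- fiber_cauchy_stress(lam_e, mat)
  prod <- collagen_production_rate(point$rho_c, sigma, sigma_h, Gamma, params)
  deg <- collagen_degradation_rate(point$rho_c, Gamma, params)
  turnover <- if (point$rho_c > 0) prod / point$rho_c + 1 / params$T_c else 1 / params$T_c

  point$rho_c <- point$rho_c + h * (prod + deg)
  point$rho_e <- point$rho_e + h * elastin_degradation_rate(point$rho_e, Gamma, params)
  upd <- update_remodeling_stretch(point$lam_r, lam_fib_add, mat, turnover, h,
                                   deposition_stretch)
  point$lam_r <- upd$lam_r
  point$sigma_f <- upd$sigma_f
  point$lam_e <- upd$lam_e
  point
}

#' Integrate the G&R kinetics of a single material point
#'
#' Evolves constituent densities and the collagen remodeling stretch of one
#' material point under a prescribed, fixed total deformation (given through
#' the additional fiber stretch). Used directly by refined-integration
#' convergence checks; [step_gr()] runs the same kinetics per region between
#' structural re-equilibrations.
#'
#' @param point List with `rho_e`, `rho_c`, `lam_r`.
#' @param mat A [layer_material()].
#' @param params A [growth_parameters()].
#' @param burden Function `burden(a, b)` returning the local inflammatory
#'   burden averaged over the substep \[a, b\] (already including the
#'   spatial multiplier); see [gamma_burden_average()].
#' @param days Total integration time, days.
#' @param substeps_per_day Number of forward-Euler substeps per day.
#' @param lam_fib_add Fixed additional fiber stretch.
#' @param t0 Start time, days.
#' @param deposition_stretch Collagen deposition stretch.
#' @return The point after integration, with a `trajectory` attribute
#'   (data.frame of time, rho_e, rho_c, lam_r, sigma_f).
#' @export
integrate_gr_point <- function(point, mat, params, burden, days,
                               substeps_per_day = 1, lam_fib_add = 1,
                               t0 = 0, deposition_stretch = 1.10) {
  n <- round(days * substeps_per_day)
  h <- days / n
  traj <- matrix(NA_real_, nrow = n + 1, ncol = 5,
                 dimnames = list(NULL, c("time", "rho_e", "rho_c", "lam_r",
                                         "sigma_f")))
  lam_e <- deposition_stretch * lam_fib_add / point$lam_r
  traj[1, ] <- c(t0, point$rho_e, point$rho_c, point$lam_r,
                 fiber_cauchy_stress(lam_e, mat))
  for (k in seq_len(n)) {
    s_end <- t0 + k * h
    point <- gr_point_substep(point, mat, params, burden(s_end - h, s_end), h,
                              lam_fib_add, deposition_stretch)
    traj[k + 1, ] <- c(s_end, point$rho_e, point$rho_c, point$lam_r,
                       point$sigma_f)
  }
  attr(point, "trajectory") <- as.data.frame(traj)
  point
}

#' Advance the wall state by one growth step
#'
#' One 3-day growth step: (1) evaluate the inflammatory burden per region
#' (exact substep averages), (2) integrate the turnover kinetics with daily
#' forward-Euler substeps at frozen macroscopic kinematics, (3) update the
#' per-region growth factor from the new total density, (4) update the
#' collagen remodeling stretch by turnover-paced stress relaxation, and
#' (5) re-equilibrate the remaining wall, the intact arc and the detached
#' membrane. Failures (density collapse, growth factor outside \[0.2, 5\],
#' elastic fiber stretch above 1.5, equilibrium bracket failure, non-finite
#' state) are recorded in the returned state's status, not raised.
#'
#' @param state A `wall_state` (healthy or dissected), equilibrated.
#' @param params A [growth_parameters()].
#' @param pattern An [inflammation_pattern()].
#' @param dt Growth step, days (default 3).
#' @param substeps_per_day Kinetics substeps per day (default 1).
#' @param step_index Step number recorded on failure.
#' @return The state at `state$time + dt` (or with a failure status).
#' @export
step_gr <- function(state, params, pattern, dt = 3, substeps_per_day = 1,
                    step_index = NA_integer_) {
  if (!state_ok(state)) return(state)
  s0 <- state$time
  nsub <- max(1L, round(dt * substeps_per_day))
  h <- dt / nsub
  dep_c <- state$deposition$collagen_deposition_stretch

  advance_region <- function(reg) {
    mult <- inflammation_field(pattern, reg$label)
    ca2 <- cos(reg$mat$alpha)^2
    lam_fib_add <- sqrt(reg$lam_theta_add^2 * ca2 + (1 - ca2))
    point <- list(rho_e = reg$rho_e, rho_c = reg$rho_c, lam_r = reg$lam_r)
    for (k in seq_len(nsub)) {
      G <- if (mult > 0) {
        mult * gamma_burden_average(pattern, s0 + (k - 1) * h, s0 + k * h,
                                    delta = params$delta, beta = params$beta)
      } else 0
      point <- gr_point_substep(point, reg$mat, params, G, h, lam_fib_add,
                                dep_c)
    }
    reg$rho_e <- point$rho_e
    reg$rho_c <- point$rho_c
    reg$lam_r <- point$lam_r
    reg$g <- (reg$rho_e + 2 * reg$rho_c) / reg$rho_tot0
    reg
  }

  all_regions <- function(st) {
    regs <- unlist(lapply(st$sectors, `[[`, "regions"), recursive = FALSE)
    if (!is.null(st$membrane)) regs <- c(regs, list(st$membrane$region))
    regs
  }

  for (sn in names(state$sectors)) {
    state$sectors[[sn]]$regions <-
      lapply(state$sectors[[sn]]$regions, advance_region)
  }
  if (!is.null(state$membrane)) {
    state$membrane$region <- advance_region(state$membrane$region)
  }

  for (reg in all_regions(state)) {
    vals <- c(reg$rho_e, reg$rho_c, reg$lam_r, reg$g)
    if (!all(is.finite(vals))) {
      return(state_failed(state, "nonfinite_state", step_index))
    }
    if (reg$rho_c <= 1e-6 || reg$rho_e <= 1e-6) {
      return(state_failed(state, "density_floor", step_index))
    }
    if (reg$g < 0.2 || reg$g > 5) {
      return(state_failed(state, "growth_factor_bounds", step_index))
    }
  }

  state$time <- s0 + dt
  state <- equilibrate_wall_state(state, step_index = step_index)
  state
}
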