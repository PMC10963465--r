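#' Simulation schedule
#'
#' @param n_steps Number of growth steps (default 30).
#' @param dt_days Growth step length, days (default 3).
#' @param report_days Days at which snapshots are captured; must lie on the
#'   step grid.
#' @return An object of class `schedule_spec`.
#' @export
schedule_spec <- function(n_steps = 30, dt_days = 3,
                          report_days = c(0, 15, 42, 90)) {
  if (n_steps < 1 || dt_days <= 0) {
    stop("schedule_spec: need n_steps >= 1 and dt_days > 0", call. = FALSE)
  }
  grid <- seq(0, n_steps * dt_days, by = dt_days)
  if (!all(report_days %in% grid)) {
    stop("schedule_spec: report_days must lie on the step grid ",
         "(multiples of dt_days up to n_steps*dt_days)", call. = FALSE)
  }
  structure(list(n_steps = as.integer(n_steps), dt_days = dt_days,
                 report_days = sort(unique(report_days))),
            class = "schedule_spec")
}

#' Re-equilibrate a pressurized wall sector
#'
#' Solves the current inner radius of a cylindrical sector (incompressible
#' deformation superposed on radial growth, fixed axial stretch) so that
#' radial equilibrium holds between the luminal pressure and a traction-free
#' outer surface. Equivalent global form:
#' \eqn{\int \sigma_{\theta\theta}\, dr = P\, r_i}.
#'
#' @param state A `wall_state`.
#' @param sector Sector name ("dissected", "intact", or "wall" for the
#'   healthy cylinder).
#' @param pressure Luminal pressure, MPa; defaults to the diastolic pressure
#'   of the state's deposition spec.
#' @return The state with the sector re-solved and its cached kinematics and
#'   stresses refreshed; a bracket failure is recorded in the status.
#' @export
equilibrate_remaining_wall <- function(state, sector = "dissected",
                                       pressure = state$deposition$diastolic_pressure) {
  sec <- state$sectors[[sector]]
  if (is.null(sec)) stop("equilibrate_remaining_wall: no sector '", sector, "'",
                         call. = FALSE)
  root <- solve_sector_inner_radius(sec$regions, state$Gth, state$deposition,
                                    pressure)
  if (is.null(root)) {
    return(state_failed(state, paste0("equilibrium_solve:", sector)))
  }
  sec$r_inner <- root
  state$sectors[[sector]] <- refresh_sector(sec, state$Gth, state$deposition)
  state
}

#' Re-equilibrate the detached membrane
#'
#' The dissected membrane carries no net transmural load; its circumferential
#' stretch (an independent degree of freedom) is solved so that the total
#' mixture circumferential Cauchy stress vanishes at fixed axial stretch.
#' Thickness follows from radial growth and incompressibility:
#' reference thickness x growth factor / circumferential stretch.
#'
#' @param state A dissected `wall_state`.
#' @return The state with the membrane re-solved; a root-bracket failure in
#'   (0.3, 2.0) is recorded in the status.
#' @export
equilibrate_membrane <- function(state) {
  if (is.null(state$membrane)) {
    stop("equilibrate_membrane: state has no detached membrane", call. = FALSE)
  }
  root <- solve_membrane_stretch(state$membrane$region, state$Gth,
                                 state$deposition)
  if (is.null(root)) {
    return(state_failed(state, "equilibrium_solve:membrane"))
  }
  state$membrane$lam_theta <- root
  state$membrane <- refresh_membrane(state$membrane, state$Gth,
                                     state$deposition)
  state
}

# Equilibrate every structural sub-problem of a state and run the elastic
# failure checks. Used after dissection and after every growth step.
equilibrate_wall_state <- function(state, step_index = NA_integer_) {
  for (sn in names(state$sectors)) {
    state <- equilibrate_remaining_wall(state, sector = sn)
    if (!state_ok(state)) {
      state$status$step <- step_index
      return(state)
    }
  }
  if (!is.null(state$membrane)) {
    state <- equilibrate_membrane(state)
    if (!state_ok(state)) {
      state$status$step <- step_index
      return(state)
    }
  }
  regs <- unlist(lapply(state$sectors, `[[`, "regions"), recursive = FALSE)
  if (!is.null(state$membrane)) regs <- c(regs, list(state$membrane$region))
  for (reg in regs) {
    if (!is.finite(reg$lam_e)) {
      return(state_failed(state, "nonfinite_state", step_index))
    }
    if (reg$mat$k1 > 0 && reg$lam_e > 1.5) {
      return(state_failed(state, "fiber_stretch", step_index))
    }
  }
  state
}

#' Through-wall hoop stress profile of a sector
#'
#' Reconstructs the radial and circumferential Cauchy stress through a
#' sector's wall by integrating the radial equilibrium equation
#' \eqn{d\sigma_{rr}/dr = (\sigma_{\theta\theta} - \sigma_{rr})/r} from the
#' pressurized inner surface, using nested Gauss-Legendre quadrature. Also
#' returns both sides of the global force balance
#' \eqn{\int \sigma_{\theta\theta}\, dr} vs \eqn{P\, r_i}.
#'
#' @param state An equilibrated `wall_state`.
#' @param sector Sector name.
#' @param n_gauss Quadrature order per region.
#' @param pressure Luminal pressure, MPa.
#' @return A data.frame (`r`, `sigma_rr`, `sigma_tt`, `region`) with
#'   attributes `int_hoop` and `P_ri`.
#' @export
wall_stress_profile <- function(state, sector = "wall", n_gauss = 24,
                                pressure = state$deposition$diastolic_pressure) {
  sec <- state$sectors[[sector]]
  if (is.null(sec)) stop("wall_stress_profile: no sector '", sector, "'",
                         call. = FALSE)
  regions <- sec$regions
  rho_i <- sec$r_inner
  Gth <- state$Gth
  dep <- state$deposition
  gl <- gl_unit(n_gauss)

  q_at <- function(R, j) {
    rho <- sector_rho_of_R(regions, rho_i, R, j)
    region_q(rho / R, regions[[j]], Gth, dep)
  }
  # sigma_rr(R in region j) = -P + int_{R_i}^{R} q g R'/rho^2 dR'
  sigma_rr_at <- function(R, j) {
    acc <- -pressure
    for (k in seq_len(j)) {
      a <- regions[[k]]$ref_r[1]
      b <- if (k < j) regions[[k]]$ref_r[2] else R
      if (b <= a) next
      Rn <- a + (b - a) * gl$x
      w <- (b - a) * gl$w
      rho <- sector_rho_of_R(regions, rho_i, Rn, k)
      q <- region_q(rho / Rn, regions[[k]], Gth, dep)
      acc <- acc + sum(w * q * regions[[k]]$g * Rn / rho^2)
    }
    acc
  }

  rows <- list()
  int_hoop <- 0
  for (j in seq_along(regions)) {
    a <- regions[[j]]$ref_r[1]
    b <- regions[[j]]$ref_r[2]
    Rn <- a + (b - a) * gl$x
    w <- (b - a) * gl$w
    rho <- sector_rho_of_R(regions, rho_i, Rn, j)
    q <- q_at(Rn, j)
    srr <- vapply(Rn, sigma_rr_at, numeric(1), j = j)
    stt <- q + srr
    # integral in the current configuration: drho = g R / rho dR
    int_hoop <- int_hoop + sum(w * stt * regions[[j]]$g * Rn / rho)
    rows[[j]] <- data.frame(r = rho, sigma_rr = srr, sigma_tt = stt,
                            region = regions[[j]]$label)
  }
  out <- do.call(rbind, rows)
  attr(out, "int_hoop") <- int_hoop
  attr(out, "P_ri") <- pressure * rho_i
  out
}

#' Run one full growth-and-remodeling simulation
#'
#' Executes the pipeline prestress -> dissect -> 30 growth steps, capturing
#' wall-state snapshots at the report days and a per-step time series.
#' Failures are recorded in the result status (never raised), and the
#' partial result up to the failed step is returned. Deterministic given its
#' inputs.
#'
#' @param params A [growth_parameters()].
#' @param pattern An [inflammation_pattern()] (its delta/beta default to the
#'   values in `params`).
#' @param geometry A [geometry_spec()] or [build_reference_geometry()] result.
#' @param materials List with `media` and `adventitia` [layer_material()]s.
#' @param deposition A [deposition_spec()].
#' @param schedule A [schedule_spec()].
#' @param dissected If FALSE, the healthy cylinder is evolved without
#'   dissection (homeostasis check).
#' @param substeps_per_day Kinetics substeps per day.
#' @return An object of class `simulation_result`: list with `params`,
#'   `pattern`, `schedule`, `snapshots` (named by day), `timeseries`
#'   (data.frame), `status`, `converged`, `n_steps_completed`.
#' @export
run_simulation <- function(params, pattern,
                           geometry = geometry_spec(),
                           materials = list(media = medial_material(),
                                            adventitia = adventitial_material()),
                           deposition = deposition_spec(),
                           schedule = schedule_spec(),
                           dissected = TRUE,
                           substeps_per_day = 1) {
  decomp <- if (inherits(geometry, "region_decomposition")) geometry else
    build_reference_geometry(geometry)
  state <- solve_healthy_invivo_state(decomp, materials, deposition)
  if (dissected) state <- dissect(state)

  snapshots <- list()
  ts_rows <- list()
  record <- function(st, day) {
    row <- summarize_wall_state(st)
    ts_rows[[length(ts_rows) + 1L]] <<- row
    if (day %in% schedule$report_days) {
      snapshots[[as.character(day)]] <<- st
    }
  }
  if (state_ok(state)) record(state, 0)

  n_done <- 0L
  if (state_ok(state)) {
    for (k in seq_len(schedule$n_steps)) {
      state <- step_gr(state, params, pattern, dt = schedule$dt_days,
                       substeps_per_day = substeps_per_day, step_index = k)
      if (!state_ok(state)) break
      n_done <- k
      record(state, k * schedule$dt_days)
    }
  }

  timeseries <- if (length(ts_rows)) do.call(rbind, ts_rows) else NULL
  structure(
    list(params = params, pattern = pattern, schedule = schedule,
         snapshots = snapshots, timeseries = timeseries,
         status = state$status,
         converged = state_ok(state) && n_done == schedule$n_steps,
         n_steps_completed = n_done,
         final_state = state),
    class = "simulation_result"
  )
}

# One time-series row of scalar summaries of a wall state.
summarize_wall_state <- function(state) {
  d <- diameters(state)
  memb <- state$membrane
  memb_reg <- if (!is.null(memb)) memb$region else NULL
  wall_reg <- if (state$dissected) state$sectors$dissected$regions[[1]] else
    state$sectors$wall$regions[[1]]
  data.frame(
    time_days = state$time,
    D_tot_mm = d[["D_tot"]],
    D_TL_mm = d[["D_TL"]],
    D_FL_mm = d[["D_FL"]],
    membrane_thickness_mm = if (!is.null(memb)) memb$thickness else NA_real_,
    membrane_lam_theta = if (!is.null(memb)) memb$lam_theta else NA_real_,
    membrane_rho_e = if (!is.null(memb_reg)) memb_reg$rho_e else NA_real_,
    membrane_rho_c_total = if (!is.null(memb_reg)) 2 * memb_reg$rho_c else NA_real_,
    membrane_growth_factor = if (!is.null(memb_reg)) memb_reg$g else NA_real_,
    membrane_sigma_f_MPa = if (!is.null(memb_reg)) memb_reg$sigma_f else NA_real_,
    wall_sigma_f_MPa = wall_reg$sigma_f,
    wall_lam_e = wall_reg$lam_e
  )
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("G&R simulation (", x$pattern$duration, "/", x$pattern$location, ")\n",
      sep = "")
  cat(sprintf("  steps completed: %d/%d; converged: %s\n",
              x$n_steps_completed, x$schedule$n_steps, x$converged))
  if (!x$converged) {
    cat(sprintf("  failure: %s at step %s\n", x$status$reason,
                format(x$status$step)))
  }
  if (!is.null(x$timeseries)) {
    last <- x$timeseries[nrow(x$timeseries), ]
    cat(sprintf("  day %g: D_tot %.2f mm, membrane thickness %.3f mm\n",
                last$time_days, last$D_tot_mm, last$membrane_thickness_mm))
  }
  invisible(x)
}
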