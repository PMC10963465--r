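# Internal mechanics of the reduced structural surrogate.
#
# The remaining wall (and the intact arc) is an incompressible thick-walled
# cylinder at fixed axial stretch; the dissected membrane is a detached
# zero-net-load lamella. All constituent kinematics reduce to functions of
# the additional circumferential stretch lt = lambda_theta relative to the in
# vivo reference configuration:
#   elastin:  lam_theta^e = lt * Gth,  lam_r^e = 1/(lt * dep_ez * Gth),
#             lam_z^e = dep_ez                     (exactly incompressible)
#   collagen: lam_e = dep_c * sqrt(lt^2 cos^2 a + sin^2 a) / lam_r
# where Gth is the solved elastin circumferential deposition stretch, dep_ez
# the elastin axial deposition stretch, dep_c the collagen deposition
# stretch and lam_r the collagen remodeling stretch. Growth is radial: the
# local volume ratio equals the region growth factor g, and the radial map
# of a cylindrical sector satisfies rho^2(R) = rho_i^2 + g (R^2 - R_i^2)
# per region (axial stretch fixed at the in vivo value).

.gl_cache <- new.env(parent = emptyenv())

# Gauss-Legendre nodes/weights on [0, 1], cached by order.
gl_unit <- function(n) {
  key <- as.character(n)
  got <- .gl_cache[[key]]
  if (is.null(got)) {
    gl <- pracma::gaussLegendre(n, 0, 1)
    got <- list(x = gl$x, w = gl$w)
    .gl_cache[[key]] <- got
  }
  got
}

# Circumferential-minus-radial Cauchy stress difference q(lt) of a region's
# mixture (reaction pressure cancels in the difference). Vectorized over lt.
region_q <- function(lt, reg, Gth, dep) {
  mat <- reg$mat
  lte <- lt * Gth
  lre <- 1 / (lt * dep$elastin_axial_deposition_stretch * Gth)
  q <- reg$rho_e * 2 * (mat$c10 / mat$rho0_e) * (lte^2 - lre^2)
  if (mat$k1 > 0) {
    ca2 <- cos(mat$alpha)^2
    sa2 <- 1 - ca2
    lfib2 <- lt^2 * ca2 + sa2
    lam_e <- dep$collagen_deposition_stretch * sqrt(lfib2) / reg$lam_r
    sf <- fiber_cauchy_stress(lam_e, mat)
    q <- q + 2 * reg$rho_c * sf * (lt^2 * ca2 / lfib2)
  }
  q
}

# Collagen elastic fiber stretch of a region at additional stretch lt.
region_lam_e <- function(lt, reg, dep) {
  ca2 <- cos(reg$mat$alpha)^2
  lfib2 <- lt^2 * ca2 + (1 - ca2)
  dep$collagen_deposition_stretch * sqrt(lfib2) / reg$lam_r
}

# Current radius rho(R) within a sector, given the current inner radius.
# regions must be in increasing radial order and radially contiguous.
sector_rho_of_R <- function(regions, rho_i, R, region_index) {
  base <- rho_i^2
  Ri <- regions[[1]]$ref_r[1]
  k <- 1
  while (k < region_index) {
    rr <- regions[[k]]$ref_r
    base <- base + regions[[k]]$g * (rr[2]^2 - rr[1]^2)
    k <- k + 1
  }
  a <- regions[[region_index]]$ref_r[1]
  sqrt(base + regions[[region_index]]$g * (R^2 - a^2))
}

# Outer-boundary residual of radial equilibrium for a pressurized sector:
#   integral over the wall of (sigma_tt - sigma_rr)/rho drho  -  P.
# Root in rho_i gives sigma_rr(outer) = 0 with sigma_rr(inner) = -P.
sector_residual <- function(rho_i, regions, Gth, dep, pressure, n_gauss = 12) {
  gl <- gl_unit(n_gauss)
  total <- 0
  for (j in seq_along(regions)) {
    reg <- regions[[j]]
    a <- reg$ref_r[1]
    b <- reg$ref_r[2]
    R <- a + (b - a) * gl$x
    w <- (b - a) * gl$w
    rho <- sector_rho_of_R(regions, rho_i, R, j)
    lt <- rho / R
    q <- region_q(lt, reg, Gth, dep)
    total <- total + sum(w * q * reg$g * R / rho^2)
  }
  total - pressure
}

# Solve the sector inner radius. Returns the radius, or NULL when no root
# lies in the bracket (recorded by the caller as a sample failure).
solve_sector_inner_radius <- function(regions, Gth, dep, pressure,
                                      bracket = c(0.5, 2.0), n_gauss = 12,
                                      tol = 1e-12) {
  Ri <- regions[[1]]$ref_r[1]
  lo <- bracket[1] * Ri
  hi <- bracket[2] * Ri
  f <- function(x) sector_residual(x, regions, Gth, dep, pressure, n_gauss)
  flo <- f(lo)
  fhi <- f(hi)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) return(NULL)
  stats::uniroot(f, c(lo, hi), f.lower = flo, f.upper = fhi, tol = tol)$root
}

# Net circumferential Cauchy stress of the detached membrane lamella at
# additional circumferential stretch lt (plane stress: sigma_rr = 0 fixes
# the reaction pressure, so the net hoop stress equals q).
membrane_net_hoop <- function(lt, reg, Gth, dep) {
  region_q(lt, reg, Gth, dep)
}

solve_membrane_stretch <- function(reg, Gth, dep, bracket = c(0.3, 2.0),
                                   tol = 1e-12) {
  f <- function(lt) membrane_net_hoop(lt, reg, Gth, dep)
  flo <- f(bracket[1])
  fhi <- f(bracket[2])
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) return(NULL)
  stats::uniroot(f, bracket, f.lower = flo, f.upper = fhi, tol = tol)$root
}

# Update a sector's cached kinematics after an equilibrium solve.
refresh_sector <- function(sector, Gth, dep) {
  rho_prev <- sector$r_inner
  for (j in seq_along(sector$regions)) {
    reg <- sector$regions[[j]]
    a <- reg$ref_r[1]
    b <- reg$ref_r[2]
    rho_a <- rho_prev
    rho_b <- sqrt(rho_a^2 + reg$g * (b^2 - a^2))
    Rm <- (a + b) / 2
    rho_m <- sqrt(rho_a^2 + reg$g * (Rm^2 - a^2))
    lt <- rho_m / Rm
    lam_e <- region_lam_e(lt, reg, dep)
    reg$cur_r <- c(rho_a, rho_b)
    reg$lam_theta_add <- lt
    reg$lam_e <- lam_e
    reg$sigma_f <- fiber_cauchy_stress(lam_e, reg$mat)
    sector$regions[[j]] <- reg
    rho_prev <- rho_b
  }
  sector
}

refresh_membrane <- function(membrane, Gth, dep) {
  reg <- membrane$region
  lt <- membrane$lam_theta
  lam_e <- region_lam_e(lt, reg, dep)
  reg$lam_theta_add <- lt
  reg$lam_e <- lam_e
  reg$sigma_f <- fiber_cauchy_stress(lam_e, reg$mat)
  t_ref <- diff(reg$ref_r)
  lam_r_macro <- reg$g / lt       # axial stretch fixed; det F = g
  membrane$region <- reg
  membrane$thickness <- t_ref * lam_r_macro
  membrane$r_mid <- lt * mean(reg$ref_r)
  membrane
}

# Build an initial per-region growth-and-remodeling state from a geometry row.
new_region <- function(label, layer, r_inner, r_outer, arc_deg, mat) {
  list(label = label, layer = layer, mat = mat,
       ref_r = c(r_inner, r_outer), arc_deg = arc_deg,
       rho_e = mat$rho0_e, rho_c = mat$rho0_c,
       rho_e0 = mat$rho0_e, rho_c0 = mat$rho0_c,
       rho_tot0 = mat$rho0_e + 2 * mat$rho0_c,
       lam_r = 1, g = 1,
       lam_theta_add = 1, lam_e = NA_real_, sigma_f = NA_real_,
       cur_r = c(r_inner, r_outer))
}

state_failed <- function(state, reason, step = NA_integer_) {
  state$status <- list(ok = FALSE, reason = reason, step = step)
  state
}

state_ok <- function(state) isTRUE(state$status$ok)
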