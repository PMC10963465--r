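#' Convert mmHg to MPa
#'
#' Units are mm-MPa-N-day throughout the package; 1 mmHg = 133.322e-6 MPa.
#'
#' @param p Pressure in mmHg.
#' @return Pressure in MPa.
#' @export
mmhg_to_mpa <- function(p) p * 133.322e-6

#' Deposition-stretch specification
#'
#' New constituent mass is laid down under an elastic prestretch: 10% strain
#' along the fiber for collagen (defining the homeostatic fiber stress) and
#' 10% axially for elastin. The elastin circumferential deposition stretch is
#' not prescribed: it is the unknown solved by
#' [solve_healthy_invivo_state()] so that the prescribed in vivo geometry is
#' in radial equilibrium under the diastolic pressure; the radial one follows
#' from elastin incompressibility.
#'
#' @param collagen_deposition_stretch Elastic fiber prestretch of collagen.
#' @param elastin_axial_deposition_stretch Elastic axial prestretch of
#'   elastin; also the fixed in vivo axial stretch of the slice.
#' @param diastolic_pressure Diastolic pressure, MPa (default 80 mmHg).
#' @param axial_stretch Fixed in vivo axial stretch.
#' @return An object of class `deposition_spec`.
#' @export
deposition_spec <- function(collagen_deposition_stretch = 1.10,
                            elastin_axial_deposition_stretch = 1.10,
                            diastolic_pressure = mmhg_to_mpa(80),
                            axial_stretch = 1.10) {
  if (collagen_deposition_stretch <= 0 || elastin_axial_deposition_stretch <= 0 ||
      axial_stretch <= 0) {
    stop("deposition_spec: stretches must be > 0", call. = FALSE)
  }
  if (diastolic_pressure < 0) {
    stop("deposition_spec: pressure must be >= 0", call. = FALSE)
  }
  structure(list(collagen_deposition_stretch = collagen_deposition_stretch,
                 elastin_axial_deposition_stretch = elastin_axial_deposition_stretch,
                 diastolic_pressure = diastolic_pressure,
                 axial_stretch = axial_stretch),
            class = "deposition_spec")
}

#' Solve the prestressed healthy in vivo state
#'
#' The unloaded reference geometry coincides with the in vivo healthy wall
#' geometry; prestressing therefore amounts to finding constituent deposition
#' stretches that put exactly this configuration in radial equilibrium under
#' the diastolic pressure. Collagen carries its 10% fiber deposition strain
#' (so its stress is homeostatic everywhere) and elastin its 10% axial
#' strain; the single remaining unknown, the elastin circumferential
#' deposition stretch, is solved from the global thick-wall force balance
#' \deqn{\int_{r_i}^{r_o} \sigma_{\theta\theta}\, dr = P\, r_i.}
#'
#' @param geometry A [build_reference_geometry()] result (or a
#'   [geometry_spec()], which is decomposed first).
#' @param materials List with elements `media` and `adventitia`, each a
#'   [layer_material()].
#' @param deposition A [deposition_spec()].
#' @return A `wall_state` describing the healthy pressurized wall: regions
#'   `media` and `adventitia` spanning the full circumference, collagen
#'   fiber stress homeostatic throughout, status `ok`.
#' @export
solve_healthy_invivo_state <- function(geometry = build_reference_geometry(geometry_spec()),
                                       materials = list(media = medial_material(),
                                                        adventitia = adventitial_material()),
                                       deposition = deposition_spec()) {
  if (inherits(geometry, "geometry_spec")) {
    geometry <- build_reference_geometry(geometry)
  }
  r_i <- attr(geometry, "r_inner")
  r_m <- attr(geometry, "r_media_outer")
  r_o <- attr(geometry, "r_outer")
  regions <- list(
    new_region("media", "media", r_i, r_m, 360, materials$media),
    new_region("adventitia", "adventitia", r_m, r_o, 360, materials$adventitia)
  )
  P <- deposition$diastolic_pressure

  # At the reference configuration lt = 1, so q is constant per layer and
  # the equilibrium integral reduces to q_M log(r_m/r_i) + q_A log(r_o/r_m).
  residual <- function(Gth) {
    q_m <- region_q(1, regions[[1]], Gth, deposition)
    q_a <- region_q(1, regions[[2]], Gth, deposition)
    q_m * log(r_m / r_i) + q_a * log(r_o / r_m) - P
  }
  lo <- 0.5
  hi <- 3.0
  flo <- residual(lo)
  fhi <- residual(hi)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) {
    stop("solve_healthy_invivo_state: no equilibrium elastin prestretch in ",
         "bracket [", lo, ", ", hi, "] (prestress failure)", call. = FALSE)
  }
  Gth <- stats::uniroot(residual, c(lo, hi), f.lower = flo, f.upper = fhi,
                        tol = 1e-14)$root

  sector <- list(arc_deg = 360, regions = regions, r_inner = r_i)
  sector <- refresh_sector(sector, Gth, deposition)
  structure(
    list(time = 0,
         dissected = FALSE,
         geometry = geometry,
         materials = materials,
         deposition = deposition,
         Gth = Gth,
         sectors = list(wall = sector),
         membrane = NULL,
         status = list(ok = TRUE, reason = NULL, step = NULL)),
    class = "wall_state"
  )
}

#' Release the dissected membrane from the prestressed wall
#'
#' Creates the acute dissected state: the inner part of the media over the
#' false-lumen arc becomes a detached lamella carrying zero net transmural
#' load (the true- and false-lumen pressures on its two faces cancel), while
#' the thinner remaining wall of the dissected arc re-equilibrates under the
#' unchanged diastolic pressure. The membrane circumferential stretch is
#' re-solved so that its total mixture hoop stress vanishes at fixed axial
#' stretch; its collagen consequently drops to a quasi-stress-free state
#' while the remaining-wall fiber stress rises above homeostatic. Densities
#' and remodeling stretches are carried over unchanged (delamination
#' conserves constituent mass).
#'
#' @param healthy A converged healthy `wall_state` from
#'   [solve_healthy_invivo_state()].
#' @param geometry Optional region decomposition; defaults to the one stored
#'   in `healthy`.
#' @return A dissected `wall_state` with sectors `dissected` (remaining
#'   media + adventitia over the false-lumen arc) and `intact` (full wall
#'   over the intact arc) plus a detached `membrane`. On a failed membrane
#'   or wall solve the returned state carries a failure status instead.
#' @export
dissect <- function(healthy, geometry = healthy$geometry) {
  stopifnot(inherits(healthy, "wall_state"))
  if (healthy$dissected) stop("dissect: state is already dissected", call. = FALSE)
  if (!state_ok(healthy)) stop("dissect: healthy state not converged", call. = FALSE)
  gm <- as.data.frame(geometry)
  mats <- healthy$materials
  row_of <- function(lbl) gm[gm$label == lbl, , drop = FALSE]
  mk <- function(lbl) {
    r <- row_of(lbl)
    mat <- if (r$layer == "media") mats$media else mats$adventitia
    reg <- new_region(r$label, r$layer, r$r_inner, r$r_outer, r$arc_deg, mat)
    # carry over the (layer-uniform) healthy G&R state
    src <- healthy$sectors$wall$regions[[if (r$layer == "media") 1L else 2L]]
    reg$rho_e <- src$rho_e
    reg$rho_c <- src$rho_c
    reg$lam_r <- src$lam_r
    reg$g <- src$g
    reg
  }

  state <- healthy
  state$dissected <- TRUE
  state$sectors <- list(
    dissected = list(arc_deg = row_of("remaining_media")$arc_deg,
                     regions = list(mk("remaining_media"), mk("adventitia")),
                     r_inner = row_of("remaining_media")$r_inner),
    intact = list(arc_deg = row_of("intact_arc_media")$arc_deg,
                  regions = list(mk("intact_arc_media"),
                                 mk("intact_arc_adventitia")),
                  r_inner = attr(geometry, "r_inner"))
  )
  state$membrane <- list(region = mk("membrane"), lam_theta = 1,
                         thickness = NA_real_, r_mid = NA_real_)
  state <- equilibrate_wall_state(state)
  state
}
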