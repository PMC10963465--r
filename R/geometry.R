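#' Idealized dissected-aorta geometry specification
#'
#' Describes the unloaded reference cross-section of an idealized dissected
#' aorta: a cylindrical wall whose media contains a predefined delamination
#' plane (the future dissected membrane / intimal flap) at a given fraction of
#' the medial depth over a given circumferential arc. The unloaded shape
#' coincides with the in vivo healthy wall geometry; the false lumen only
#' opens once the membrane is released (see [dissect()]).
#'
#' @param inner_diameter Inner diameter of the wall, mm.
#' @param wall_thickness Total wall thickness, mm.
#' @param media_fraction Fraction of the wall thickness occupied by the media.
#' @param membrane_depth_fraction Radial position of the delamination plane
#'   within the media, measured from the inner surface (0.70 means the inner
#'   70% of the media delaminates and becomes the dissected membrane).
#' @param false_lumen_angle Circumferential extent of the false lumen, degrees.
#'   Must be strictly inside (0, 360): the membrane may not close the circle,
#'   a connection to the intact arc is required.
#' @param axial_length Axial length of the slice, mm. Carried only as a volume
#'   factor; the model is a generalized-plane-strain slice.
#'
#' @return An object of class `geometry_spec`.
#' @seealso [build_reference_geometry()]
#' @export
geometry_spec <- function(inner_diameter = 27.3,
                          wall_thickness = 1.90,
                          media_fraction = 0.75,
                          membrane_depth_fraction = 0.70,
                          false_lumen_angle = 245,
                          axial_length = 5) {
  check_positive <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      stop("geometry_spec: field '", nm, "' must be a single positive number",
           call. = FALSE)
    }
  }
  check_positive(inner_diameter, "inner_diameter")
  check_positive(wall_thickness, "wall_thickness")
  check_positive(axial_length, "axial_length")
  check_fraction <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
        x <= 0 || x >= 1) {
      stop("geometry_spec: field '", nm, "' must lie in (0, 1)", call. = FALSE)
    }
  }
  check_fraction(media_fraction, "media_fraction")
  check_fraction(membrane_depth_fraction, "membrane_depth_fraction")
  if (!is.numeric(false_lumen_angle) || length(false_lumen_angle) != 1L ||
      !is.finite(false_lumen_angle) ||
      false_lumen_angle <= 0 || false_lumen_angle >= 360) {
    stop("geometry_spec: field 'false_lumen_angle' must lie in (0, 360)",
         call. = FALSE)
  }
  structure(
    list(inner_diameter = inner_diameter,
         wall_thickness = wall_thickness,
         media_fraction = media_fraction,
         membrane_depth_fraction = membrane_depth_fraction,
         false_lumen_angle = false_lumen_angle,
         axial_length = axial_length),
    class = "geometry_spec"
  )
}

#' Build the reference region decomposition of the dissected wall
#'
#' Decomposes the unloaded cylindrical wall into the five regions used by the
#' growth-and-remodeling engine: the dissected membrane (inner part of the
#' media over the false-lumen arc), the remaining media and adventitia of the
#' dissected arc, and the media and adventitia of the intact arc.
#'
#' Coordinates are cylindrical (r, theta, z) with theta = 0 at the center of
#' the dissected arc. Radii are measured in mm in the unloaded reference
#' configuration, which also serves as the in vivo reference for the
#' prestressing step.
#'
#' @param spec A [geometry_spec()].
#' @return An object of class `region_decomposition`: a data.frame with one
#'   row per region (`label`, `layer`, `r_inner`, `r_outer`, `arc_deg`,
#'   `volume_mm3`) and attributes `spec`, `r_inner`, `r_outer`,
#'   `r_media_outer`, `r_membrane_outer`.
#' @export
build_reference_geometry <- function(spec) {
  if (!inherits(spec, "geometry_spec")) spec <- do.call(geometry_spec, spec)
  r_i <- spec$inner_diameter / 2
  r_o <- r_i + spec$wall_thickness
  t_media <- spec$media_fraction * spec$wall_thickness
  r_media <- r_i + t_media
  r_memb <- r_i + spec$membrane_depth_fraction * t_media
  arc_fl <- spec$false_lumen_angle
  arc_in <- 360 - arc_fl
  L <- spec$axial_length

  vol <- function(a, b, arc) (arc / 360) * pi * (b^2 - a^2) * L
  regions <- data.frame(
    label = c("membrane", "remaining_media", "adventitia",
              "intact_arc_media", "intact_arc_adventitia"),
    layer = c("media", "media", "adventitia", "media", "adventitia"),
    r_inner = c(r_i, r_memb, r_media, r_i, r_media),
    r_outer = c(r_memb, r_media, r_o, r_media, r_o),
    arc_deg = c(arc_fl, arc_fl, arc_fl, arc_in, arc_in),
    stringsAsFactors = FALSE
  )
  regions$volume_mm3 <- vol(regions$r_inner, regions$r_outer, regions$arc_deg)

  structure(regions,
            class = c("region_decomposition", "data.frame"),
            spec = spec,
            r_inner = r_i,
            r_outer = r_o,
            r_media_outer = r_media,
            r_membrane_outer = r_memb)
}

#' @export
print.region_decomposition <- function(x, ...) {
  spec <- attr(x, "spec")
  cat("Idealized dissected-aorta reference geometry\n")
  cat(sprintf("  inner radius %.4g mm, outer radius %.4g mm, slice length %g mm\n",
              attr(x, "r_inner"), attr(x, "r_outer"), spec$axial_length))
  cat(sprintf("  false lumen arc %g deg at %.0f%% of medial depth\n",
              spec$false_lumen_angle, 100 * spec$membrane_depth_fraction))
  print.data.frame(as.data.frame(x), ...)
  invisible(x)
}
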