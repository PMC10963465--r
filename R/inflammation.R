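#' Inflammation pattern
#'
#' The inflammatory burden after dissection is a prescribed function of time,
#' either transient (a pulse that rises and decays) or permanent (a
#' saturating rise), applied either to the full wall or locally to the media
#' surrounding the false lumen.
#'
#' @param duration "transient" or "permanent".
#' @param location "full" or "local".
#' @param delta Shape parameter, 1/day (> 0). Optional at construction; when
#'   simulating, delta/beta are usually carried by [growth_parameters()].
#' @param beta Dimensionless shape parameter (> 1); transient only.
#' @param include_intact_media For the local pattern: whether the media of
#'   the non-dissected arc is inflamed as well (default TRUE, reading "the
#'   media of the remaining wall" as all remaining media).
#' @return An object of class `inflammation_pattern`.
#' @export
inflammation_pattern <- function(duration = c("transient", "permanent"),
                                 location = c("full", "local"),
                                 delta = NULL, beta = NULL,
                                 include_intact_media = TRUE) {
  duration <- match.arg(duration)
  location <- match.arg(location)
  if (!is.null(delta) && (!is.finite(delta) || delta <= 0)) {
    stop("inflammation_pattern: delta must be > 0", call. = FALSE)
  }
  if (duration == "transient") {
    if (!is.null(beta) && (!is.finite(beta) || beta <= 1)) {
      stop("inflammation_pattern: beta must be > 1 for transient inflammation",
           call. = FALSE)
    }
  } else if (!is.null(beta)) {
    stop("inflammation_pattern: beta applies to transient inflammation only",
         call. = FALSE)
  }
  structure(list(duration = duration, location = location,
                 delta = delta, beta = beta,
                 include_intact_media = isTRUE(include_intact_media)),
            class = "inflammation_pattern")
}

#' Transient inflammatory burden
#'
#' \deqn{\Gamma_t(s) = \left(\frac{\delta s}{\beta - 1}\right)^{\beta-1}
#'   e^{-\delta s + \beta - 1},}
#' a pulse normalized to peak value 1 at \eqn{s^* = (\beta-1)/\delta} days,
#' with \eqn{\Gamma_t(0) = 0}.
#'
#' @param s Time since dissection, days (>= 0). Vectorized.
#' @param delta Shape parameter, 1/day (> 0).
#' @param beta Shape parameter (> 1).
#' @return Burden in \[0, 1\].
#' @export
gamma_transient <- function(s, delta, beta) {
  if (!is.finite(beta) || beta <= 1) {
    stop("gamma_transient: beta must be > 1", call. = FALSE)
  }
  if (!is.finite(delta) || delta <= 0) {
    stop("gamma_transient: delta must be > 0", call. = FALSE)
  }
  if (any(s < 0)) stop("gamma_transient: s must be >= 0", call. = FALSE)
  x <- delta * s / (beta - 1)
  out <- numeric(length(s))
  pos <- x > 0
  # exp-log form avoids overflow of x^(beta-1) for large s
  out[pos] <- exp((beta - 1) * log(x[pos]) - delta * s[pos] + beta - 1)
  out
}

#' Permanent inflammatory burden
#'
#' \deqn{\Gamma_p(s) = 1 - e^{-\delta s},} strictly increasing from 0 with
#' asymptote 1.
#'
#' @inheritParams gamma_transient
#' @return Burden in \[0, 1).
#' @export
gamma_permanent <- function(s, delta) {
  if (!is.finite(delta) || delta <= 0) {
    stop("gamma_permanent: delta must be > 0", call. = FALSE)
  }
  if (any(s < 0)) stop("gamma_permanent: s must be >= 0", call. = FALSE)
  1 - exp(-delta * s)
}

#' Evaluate the burden of a pattern/parameter combination
#'
#' @param pattern An [inflammation_pattern()].
#' @param s Time, days.
#' @param delta,beta Shape parameters; default to those stored in `pattern`.
#' @return Burden value(s).
#' @export
gamma_burden <- function(pattern, s, delta = pattern$delta,
                         beta = pattern$beta) {
  if (pattern$duration == "transient") {
    gamma_transient(s, delta, beta)
  } else {
    gamma_permanent(s, delta)
  }
}

#' Average burden over a time interval
#'
#' Exact mean of the burden over \[a, b\], from the closed-form
#' antiderivatives (regularized incomplete gamma function for the transient
#' pulse). The kinetics integrator applies each substep's average burden, so
#' density integration is insensitive to how sharply the pulse is resolved
#' by the substep grid.
#'
#' @param pattern An [inflammation_pattern()].
#' @param a,b Interval bounds, days (0 <= a < b).
#' @param delta,beta Shape parameters; default to those stored in `pattern`.
#' @return Mean burden over the interval.
#' @export
gamma_burden_average <- function(pattern, a, b, delta = pattern$delta,
                                 beta = pattern$beta) {
  if (b <= a || a < 0) {
    stop("gamma_burden_average: need 0 <= a < b", call. = FALSE)
  }
  if (pattern$duration == "transient") {
    if (!is.finite(beta) || beta <= 1) {
      stop("gamma_burden_average: beta must be > 1", call. = FALSE)
    }
    # Gamma_t(s) = C (delta s)^(beta-1) e^(-delta s),
    # C = e^(beta-1) (beta-1)^(1-beta); integral via pgamma.
    C <- exp((beta - 1) - (beta - 1) * log(beta - 1))
    int <- C * gamma(beta) / delta *
      (stats::pgamma(delta * b, shape = beta) -
         stats::pgamma(delta * a, shape = beta))
    int / (b - a)
  } else {
    1 - (exp(-delta * a) - exp(-delta * b)) / (delta * (b - a))
  }
}

#' Spatial assignment of the inflammatory burden
#'
#' Full inflammation covers the complete medial and adventitial layers;
#' local inflammation covers the dissected membrane and the remaining media
#' (by default including the media of the intact arc), leaving the
#' adventitia unaffected. Regions with multiplier 0 still undergo
#' stress-mediated growth and remodeling.
#'
#' @param pattern An [inflammation_pattern()].
#' @param region Region label: one of "membrane", "remaining_media",
#'   "adventitia", "intact_arc_media", "intact_arc_adventitia", or the
#'   pre-dissection labels "media"/"adventitia".
#' @return 0 or 1.
#' @export
inflammation_field <- function(pattern, region) {
  known <- c("membrane", "remaining_media", "adventitia",
             "intact_arc_media", "intact_arc_adventitia", "media")
  if (!region %in% known) {
    stop("inflammation_field: unknown region '", region, "'", call. = FALSE)
  }
  if (pattern$location == "full") return(1)
  medial <- region %in% c("membrane", "remaining_media", "media")
  if (medial) return(1)
  if (region == "intact_arc_media" && pattern$include_intact_media) return(1)
  0
}
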