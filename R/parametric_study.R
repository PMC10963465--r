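#' Published parameter ranges for the Latin hypercube
#'
#' Parameter bounds assembled from published homogenized-constrained-mixture
#' studies: the stress gain k_sigma \[0.00; 0.42\], inflammatory collagen
#' production gain k_gplus_c \[1.74; 24.9\], inflammatory collagen
#' degradation gain k_gminus_c \[1.41; 20.7\], inflammatory elastin
#' degradation gain k_gminus_e \[0.000; 0.0707\] per step, and the
#' inflammation shape parameters: delta \[0.0151; 0.478\] 1/day with beta
#' \[1.10; 4.64\] for transient patterns, delta \[2.77; 17.0\] 1/day (no
#' beta) for permanent patterns.
#'
#' @param duration "transient" (6 dimensions) or "permanent" (5, no beta).
#' @return Named list of `c(min, max)` ranges.
#' @export
parameter_ranges <- function(duration = c("transient", "permanent")) {
  duration <- match.arg(duration)
  base <- list(
    k_sigma = c(0.00, 0.42),
    k_gplus_c = c(1.74, 24.9),
    k_gminus_c = c(1.41, 20.7),
    k_gminus_e = c(0.000, 0.0707)
  )
  if (duration == "transient") {
    c(base, list(delta = c(0.0151, 0.478), beta = c(1.10, 4.64)))
  } else {
    c(base, list(delta = c(2.77, 17.0)))
  }
}

#' Latin-hypercube sample of the G&R parameter space
#'
#' Stratified uniform sampling: each marginal is divided into n equal
#' strata holding exactly one (jittered) sample. Transient patterns sample
#' 6 dimensions, permanent ones 5 (no beta); the same table is meant to be
#' reused for the full and local locations of a given duration.
#'
#' @param n Number of samples (>= 1).
#' @param duration "transient" or "permanent".
#' @param seed Integer RNG seed, recorded on the output.
#' @param ranges Named list of `c(min, max)`; defaults to
#'   [parameter_ranges()] for `duration`.
#' @return Object of class `sample_table`: data.frame with a `sample` id
#'   column and one column per parameter; attributes `seed`, `duration`,
#'   `ranges`.
#' @export
latin_hypercube <- function(n, duration = c("transient", "permanent"),
                            seed = 1L, ranges = parameter_ranges(duration)) {
  duration <- match.arg(duration)
  if (n < 1) stop("latin_hypercube: n must be >= 1", call. = FALSE)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || !all(is.finite(r)) || r[1] >= r[2]) {
      stop("latin_hypercube: invalid range for '", nm,
           "' (need min < max)", call. = FALSE)
    }
  }
  set.seed(as.integer(seed))
  U <- lhs::randomLHS(n, length(ranges))
  tab <- as.data.frame(
    vapply(seq_along(ranges), function(j) {
      r <- ranges[[j]]
      r[1] + (r[2] - r[1]) * U[, j]
    }, numeric(n))
  )
  names(tab) <- names(ranges)
  tab <- cbind(sample = seq_len(n), tab)
  structure(tab, class = c("sample_table", "data.frame"),
            seed = as.integer(seed), duration = duration, ranges = ranges)
}

# growth_parameters object for one row of a sample table
params_from_row <- function(row, duration) {
  growth_parameters(
    k_sigma = row$k_sigma, k_gplus_c = row$k_gplus_c,
    k_gminus_c = row$k_gminus_c, k_gminus_e = row$k_gminus_e,
    delta = row$delta,
    beta = if (duration == "transient") row$beta else NULL
  )
}

#' Run the parametric study over a sample table
#'
#' Runs one G&R simulation per Latin-hypercube sample (samples are
#' independent; any execution order gives identical aggregates), computes
#' the outcome record of each, and aggregates the success rate, the
#' clinical-range subset, and the parameter-space reduction of the
#' converged and clinical subsets.
#'
#' @param samples A [latin_hypercube()] table.
#' @param location "full" or "local" inflammation.
#' @param geometry,materials,deposition,schedule Model configuration;
#'   defaults reproduce the reference setup.
#' @param ranges Clinical ranges for classification.
#' @param include_intact_media Passed to [inflammation_pattern()].
#' @param progress Print one line per sample.
#' @return Object of class `study_result`: list with `outcomes` (one row
#'   per sample, prefixed by the sampled parameters), `success_rate`,
#'   `n_converged`, `n_clinical`, `reduction_converged`,
#'   `reduction_clinical` (each a [parameter_space_reduction()] result),
#'   `location`, `duration`, `seed`.
#' @export
run_study <- function(samples, location = c("full", "local"),
                      geometry = geometry_spec(),
                      materials = list(media = medial_material(),
                                       adventitia = adventitial_material()),
                      deposition = deposition_spec(),
                      schedule = schedule_spec(),
                      ranges = clinical_ranges(),
                      include_intact_media = TRUE,
                      progress = FALSE) {
  location <- match.arg(location)
  duration <- attr(samples, "duration")
  param_names <- names(attr(samples, "ranges"))
  pattern <- inflammation_pattern(duration, location,
                                  include_intact_media = include_intact_media)
  decomp <- if (inherits(geometry, "region_decomposition")) geometry else
    build_reference_geometry(geometry)

  rows <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    row <- samples[i, , drop = FALSE]
    params <- params_from_row(row, duration)
    res <- run_simulation(params, pattern, geometry = decomp,
                          materials = materials, deposition = deposition,
                          schedule = schedule)
    oc <- outcome_record(res, ranges)
    rows[[i]] <- cbind(row, oc, row.names = NULL)
    if (progress) {
      message(sprintf("sample %d/%d: converged=%s clinical=%s",
                      i, nrow(samples), oc$converged, oc$in_clinical_range))
    }
  }
  outcomes <- do.call(rbind, rows)

  conv <- outcomes[outcomes$converged, , drop = FALSE]
  clin <- outcomes[outcomes$converged & outcomes$in_clinical_range, , drop = FALSE]
  red <- function(sub) {
    parameter_space_reduction(sub[, param_names, drop = FALSE],
                              attr(samples, "ranges"))
  }
  structure(
    list(outcomes = outcomes,
         success_rate = nrow(conv) / nrow(outcomes),
         n_converged = nrow(conv),
         n_clinical = nrow(clin),
         reduction_converged = red(conv),
         reduction_clinical = red(clin),
         location = location, duration = duration,
         seed = attr(samples, "seed")),
    class = "study_result"
  )
}

#' Parameter-space reduction of a sample subset
#'
#' Per parameter, the width of the subset's value range relative to the
#' initial sampling range; the product over all sampled parameters is the
#' fraction of the initial parameter space the subset occupies.
#'
#' @param subset data.frame of parameter values (columns must match
#'   `names(ranges)`).
#' @param ranges Named list of initial `c(min, max)` ranges.
#' @return List with `relative_widths` (named numeric) and `product`; for
#'   an empty subset both are NA with `n = 0`.
#' @export
parameter_space_reduction <- function(subset, ranges) {
  if (is.null(subset) || nrow(subset) == 0L) {
    return(list(relative_widths = stats::setNames(
      rep(NA_real_, length(ranges)), names(ranges)),
      product = NA_real_, n = 0L))
  }
  widths <- vapply(names(ranges), function(nm) {
    r <- ranges[[nm]]
    (max(subset[[nm]]) - min(subset[[nm]])) / (r[2] - r[1])
  }, numeric(1))
  list(relative_widths = widths, product = prod(widths), n = nrow(subset))
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("G&R parametric study: %s/%s, n = %d (seed %d)\n",
              x$duration, x$location, nrow(x$outcomes), x$seed))
  cat(sprintf("  converged: %d (%.1f%%); within clinical ranges: %d\n",
              x$n_converged, 100 * x$success_rate, x$n_clinical))
  if (!is.na(x$reduction_converged$product)) {
    cat(sprintf("  parameter space reduced to %.1f%% (converged), %s (clinical)\n",
                100 * x$reduction_converged$product,
                if (is.na(x$reduction_clinical$product)) "n/a" else
                  sprintf("%.1f%%", 100 * x$reduction_clinical$product)))
  }
  invisible(x)
}
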