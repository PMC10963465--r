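#' Extended clinical membrane thickening ranges
#'
#' Published thickening-rate confidence intervals per dissection phase,
#' widened by 4 mm/year of CT measurement uncertainty: acute
#' \[-3.50; 6.09\], subacute \[-4.13; 5.09\], chronic \[-3.99; 4.03\]
#' mm/year. Bounds are inclusive (closed intervals).
#'
#' @param acute,subacute,chronic Numeric `c(lower, upper)`, mm/year.
#' @return Object of class `clinical_ranges`.
#' @export
clinical_ranges <- function(acute = c(-3.50, 6.09),
                            subacute = c(-4.13, 5.09),
                            chronic = c(-3.99, 4.03)) {
  chk <- function(x, nm) {
    if (length(x) != 2L || !all(is.finite(x)) || x[1] >= x[2]) {
      stop("clinical_ranges: '", nm, "' must be c(lower, upper) with lower < upper",
           call. = FALSE)
    }
  }
  chk(acute, "acute"); chk(subacute, "subacute"); chk(chronic, "chronic")
  structure(list(acute = acute, subacute = subacute, chronic = chronic),
            class = "clinical_ranges")
}

#' Dissected-membrane thickening rate
#'
#' \eqn{R_T = (T^i_{DM} - T^j_{DM})/(i - j)} in mm/day between two report
#' days, with the annualized value (x 365) for comparison against clinical
#' ranges.
#'
#' @param T_i,T_j Membrane thickness at days `day_i` and `day_j`, mm.
#' @param day_i,day_j Days, with `day_i > day_j`.
#' @return Named vector `c(mm_per_day = , mm_per_year = )`.
#' @export
thickening_rate <- function(T_i, T_j, day_i, day_j) {
  if (day_i <= day_j) stop("thickening_rate: need day_i > day_j", call. = FALSE)
  per_day <- (T_i - T_j) / (day_i - day_j)
  c(mm_per_day = per_day, mm_per_year = per_day * 365)
}

#' Classify phase-wise thickening rates against the clinical ranges
#'
#' TRUE iff all three phase rates are present (i.e. the simulation converged
#' through all growth steps) and each lies within its extended clinical
#' range, bounds inclusive.
#'
#' @param rates Named numeric: `acute`, `subacute`, `chronic`, mm/year.
#'   Missing or NA phases classify as FALSE.
#' @param ranges A [clinical_ranges()].
#' @return Logical with attribute `reason` when FALSE.
#' @export
classify_clinical <- function(rates, ranges = clinical_ranges()) {
  phases <- c("acute", "subacute", "chronic")
  for (ph in phases) {
    r <- rates[[ph]]
    if (is.null(r) || !is.finite(r)) {
      out <- FALSE
      attr(out, "reason") <- paste0("missing_phase:", ph)
      return(out)
    }
  }
  for (ph in phases) {
    rng <- ranges[[ph]]
    if (rates[[ph]] < rng[1] || rates[[ph]] > rng[2]) {
      out <- FALSE
      attr(out, "reason") <- paste0("out_of_range:", ph)
      return(out)
    }
  }
  TRUE
}

#' Lumen diameters along the measurement line through the dissected arc
#'
#' The total diameter is the cross-sectional extent of the intraluminal
#' space: intact-side inner radius plus dissected-side (remaining wall)
#' inner radius. The true lumen spans from the intact-side inner wall to
#' the membrane mid-surface; the false lumen is the remainder, so
#' D_TL + D_FL = D_tot holds exactly by construction.
#'
#' @param state An equilibrated `wall_state`.
#' @return Named vector `c(D_tot = , D_TL = , D_FL = )`, mm.
#' @export
diameters <- function(state) {
  if (!state$dissected) {
    D <- 2 * state$sectors$wall$r_inner
    return(c(D_tot = D, D_TL = D, D_FL = 0))
  }
  r_dis <- state$sectors$dissected$r_inner
  r_int <- state$sectors$intact$r_inner
  r_mid <- state$membrane$r_mid
  D_tot <- r_dis + r_int
  D_TL <- r_int + r_mid
  c(D_tot = D_tot, D_TL = D_TL, D_FL = D_tot - D_TL)
}

#' Annualized diameter expansion rate
#'
#' Modeled expansion over 90 days plus extrapolation of the chronic-phase
#' rate to one year:
#' \deqn{R_e = (D^{90} - D^0) + \frac{D^{90} - D^{42}}{90 - 42}(365 - 90).}
#' For an exactly linear trajectory this collapses to 365 x the daily slope.
#'
#' @param D_0,D_42,D_90 Diameter at days 0, 42 and 90, mm.
#' @return Expansion rate, mm/year.
#' @export
expansion_rate <- function(D_0, D_42, D_90) {
  (D_90 - D_0) + (D_90 - D_42) / (90 - 42) * (365 - 90)
}

#' Constituent content of the dissected membrane
#'
#' Volume-weighted mean constituent density over the selected regions,
#' expressed relative to the initial configuration. For collagen both fiber
#' families are summed. At day 0 this equals the initial layer fractions.
#'
#' @param result A `simulation_result` with a snapshot at `day`.
#' @param constituent "elastin" or "collagen".
#' @param day Report day.
#' @param regions Region labels to average over (default the dissected
#'   membrane).
#' @return Content as fraction of the initial volume.
#' @export
constituent_content <- function(result, constituent = c("elastin", "collagen"),
                                day, regions = "membrane") {
  constituent <- match.arg(constituent)
  snap <- result$snapshots[[as.character(day)]]
  if (is.null(snap)) {
    stop("constituent_content: no snapshot at day ", day, call. = FALSE)
  }
  regs <- unlist(lapply(snap$sectors, `[[`, "regions"), recursive = FALSE)
  if (!is.null(snap$membrane)) regs <- c(regs, list(snap$membrane$region))
  regs <- Filter(function(r) r$label %in% regions, regs)
  if (!length(regs)) {
    stop("constituent_content: no region matching ",
         paste(regions, collapse = ", "), call. = FALSE)
  }
  # reference volumes weight the per-region densities (densities are already
  # relative to the initial configuration)
  vols <- vapply(regs, function(r) {
    (r$arc_deg / 360) * pi * (r$ref_r[2]^2 - r$ref_r[1]^2)
  }, numeric(1))
  dens <- vapply(regs, function(r) {
    if (constituent == "elastin") r$rho_e else 2 * r$rho_c
  }, numeric(1))
  sum(vols * dens) / sum(vols)
}

#' Membrane volume ratio
#'
#' Current combined elastin + collagen volume of the dissected membrane
#' relative to its initial volume. With exactly incompressible elastic
#' behavior and unit-determinant remodeling this equals the growth factor.
#'
#' @param result A `simulation_result` with a snapshot at `day`.
#' @param day Report day (default 90).
#' @return Dimensionless volume ratio.
#' @export
membrane_volume_ratio <- function(result, day = 90) {
  snap <- result$snapshots[[as.character(day)]]
  if (is.null(snap) || is.null(snap$membrane)) {
    stop("membrane_volume_ratio: no membrane snapshot at day ", day,
         call. = FALSE)
  }
  snap$membrane$region$g
}

#' Outcome record of one simulation
#'
#' Collects the clinical-style outcome measures of a single G&R simulation:
#' phase-wise membrane thickening rates (acute day 0-15, subacute 15-42,
#' chronic 42-90; per day and annualized), diameters at the report days,
#' extrapolated expansion rates for total/true/false lumen, membrane
#' elastin and collagen content, membrane volume ratio at day 90, and the
#' clinical-range classification (only converged runs can classify TRUE).
#'
#' @param result A `simulation_result`.
#' @param ranges A [clinical_ranges()].
#' @return One-row data.frame.
#' @export
outcome_record <- function(result, ranges = clinical_ranges()) {
  days <- c(0, 15, 42, 90)
  snap_ok <- vapply(as.character(days),
                    function(d) !is.null(result$snapshots[[d]]), logical(1))
  grab <- function(day, fn) {
    if (!snap_ok[[as.character(day)]]) return(NA_real_)
    fn(result$snapshots[[as.character(day)]])
  }
  thick <- vapply(days, function(d) grab(d, function(s) s$membrane$thickness),
                  numeric(1))
  names(thick) <- days
  D <- lapply(days, function(d) {
    if (!snap_ok[[as.character(d)]]) {
      return(c(D_tot = NA_real_, D_TL = NA_real_, D_FL = NA_real_))
    }
    diameters(result$snapshots[[as.character(d)]])
  })
  names(D) <- days

  rate <- function(i, j) {
    if (is.na(thick[[as.character(i)]]) || is.na(thick[[as.character(j)]])) {
      return(c(mm_per_day = NA_real_, mm_per_year = NA_real_))
    }
    thickening_rate(thick[[as.character(i)]], thick[[as.character(j)]], i, j)
  }
  r_ac <- rate(15, 0); r_su <- rate(42, 15); r_ch <- rate(90, 42)

  exp_rate <- function(comp) {
    d0 <- D[["0"]][[comp]]; d42 <- D[["42"]][[comp]]; d90 <- D[["90"]][[comp]]
    if (any(is.na(c(d0, d42, d90)))) return(NA_real_)
    expansion_rate(d0, d42, d90)
  }

  content <- function(constituent, day) {
    if (!snap_ok[[as.character(day)]]) return(NA_real_)
    constituent_content(result, constituent, day)
  }

  rates_yr <- list(acute = r_ac[["mm_per_year"]],
                   subacute = r_su[["mm_per_year"]],
                   chronic = r_ch[["mm_per_year"]])
  clin <- classify_clinical(rates_yr, ranges)

  data.frame(
    converged = result$converged,
    n_steps_completed = result$n_steps_completed,
    failure_reason = if (result$converged) "" else
      paste0(result$status$reason, "@", result$status$step),
    R_T_acute_mm_per_day = r_ac[["mm_per_day"]],
    R_T_subacute_mm_per_day = r_su[["mm_per_day"]],
    R_T_chronic_mm_per_day = r_ch[["mm_per_day"]],
    R_T_acute_mm_per_year = r_ac[["mm_per_year"]],
    R_T_subacute_mm_per_year = r_su[["mm_per_year"]],
    R_T_chronic_mm_per_year = r_ch[["mm_per_year"]],
    T_DM_day0_mm = thick[["0"]], T_DM_day15_mm = thick[["15"]],
    T_DM_day42_mm = thick[["42"]], T_DM_day90_mm = thick[["90"]],
    D_tot_day0_mm = D[["0"]][["D_tot"]], D_tot_day90_mm = D[["90"]][["D_tot"]],
    D_TL_day0_mm = D[["0"]][["D_TL"]], D_TL_day90_mm = D[["90"]][["D_TL"]],
    D_FL_day0_mm = D[["0"]][["D_FL"]], D_FL_day90_mm = D[["90"]][["D_FL"]],
    R_e_tot_mm_per_year = exp_rate("D_tot"),
    R_e_TL_mm_per_year = exp_rate("D_TL"),
    R_e_FL_mm_per_year = exp_rate("D_FL"),
    elastin_day15 = content("elastin", 15),
    elastin_day42 = content("elastin", 42),
    elastin_day90 = content("elastin", 90),
    collagen_day15 = content("collagen", 15),
    collagen_day42 = content("collagen", 42),
    collagen_day90 = content("collagen", 90),
    membrane_volume_ratio_day90 = if (snap_ok[["90"]])
      membrane_volume_ratio(result, 90) else NA_real_,
    in_clinical_range = isTRUE(clin),
    stringsAsFactors = FALSE
  )
}
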