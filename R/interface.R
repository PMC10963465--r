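#' Default run configuration
#'
#' The full model configuration as a nested list, with defaults reproducing
#' the reference setup: 27.3 mm inner diameter, 1.90 mm wall, 75/25
#' media/adventitia, membrane at 70% of the medial depth over 245 degrees,
#' the published HGO constants, 10% deposition strains at 80 mmHg diastolic
#' pressure, a 30 x 3-day schedule with report days 0/15/42/90, the extended
#' clinical thickening ranges, and the published G&R parameter ranges for
#' the study.
#'
#' @return Named nested list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    geometry = list(inner_diameter_mm = 27.3, wall_thickness_mm = 1.90,
                    media_fraction = 0.75, membrane_depth_fraction = 0.70,
                    false_lumen_angle_deg = 245, axial_length_mm = 5),
    materials = list(
      media = list(c10_MPa = 0.015, k1_MPa = 0.12, k2 = 6.9,
                   alpha_rad = 0.79, rho0_elastin = 0.46,
                   rho0_collagen_per_family = 0.27),
      adventitia = list(c10_MPa = 0.34 * 0.015, k1_MPa = 1.17 * 0.12,
                        k2 = 6.9, alpha_rad = 1.4, rho0_elastin = 0.20,
                        rho0_collagen_per_family = 0.40)
    ),
    deposition = list(collagen_deposition_stretch = 1.10,
                      elastin_axial_deposition_stretch = 1.10,
                      diastolic_pressure_mmHg = 80,
                      axial_stretch = 1.10),
    schedule = list(n_steps = 30L, dt_days = 3,
                    report_days = c(0, 15, 42, 90)),
    pattern = list(duration = "transient", location = "local",
                   include_intact_media = TRUE),
    growth_parameters = list(k_sigma = 0.130, k_gplus_c = 5.34,
                             k_gminus_c = 3.67, k_gminus_e = 0.0533,
                             delta = 0.198, beta = 1.24, T_c_days = 101),
    clinical_ranges = list(acute = c(-3.50, 6.09), subacute = c(-4.13, 5.09),
                           chronic = c(-3.99, 4.03)),
    study = list(n = 1000L, seed = 42L)
  ), class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Omitted fields take the defaults of [default_config()]; unknown fields
#' and invalid values are rejected with a message naming the field. An
#' empty file yields the full default configuration.
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: no such file: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  merged <- merge_config(unclass(default_config()), user, prefix = NULL)
  cfg <- structure(merged, class = "run_config")
  validate_config(cfg)
  cfg
}

merge_config <- function(base, user, prefix = NULL) {
  if (!is.list(user)) {
    stop("load_config: field '", paste(prefix, collapse = "."),
         "' must be a mapping", call. = FALSE)
  }
  unknown <- setdiff(names(user), names(base))
  if (length(unknown)) {
    stop("load_config: unknown field '",
         paste(c(prefix, unknown[1]), collapse = "."), "'", call. = FALSE)
  }
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]], c(prefix, nm))
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

# Builds (and thereby validates) all model objects from a config.
validate_config <- function(cfg) {
  num <- function(x, field) {
    if (!is.numeric(x) || !all(is.finite(x))) {
      stop("load_config: field '", field, "' must be numeric, got '",
           paste(format(x), collapse = ", "), "'", call. = FALSE)
    }
    x
  }
  for (section in c("geometry", "deposition", "schedule")) {
    for (nm in names(cfg[[section]])) {
      if (nm %in% c("report_days")) next
      num(cfg[[section]][[nm]], paste(section, nm, sep = "."))
    }
  }
  invisible(config_objects(cfg))
}

#' Build model objects from a configuration
#'
#' @param cfg A `run_config`.
#' @return List with `geometry` ([geometry_spec()]), `materials`,
#'   `deposition`, `schedule`, `pattern`, `params`, `ranges`.
#' @export
config_objects <- function(cfg) {
  g <- cfg$geometry
  geometry <- geometry_spec(g$inner_diameter_mm, g$wall_thickness_mm,
                            g$media_fraction, g$membrane_depth_fraction,
                            g$false_lumen_angle_deg, g$axial_length_mm)
  lay <- function(m, layer) {
    layer_material(m$c10_MPa, m$k1_MPa, m$k2, m$alpha_rad,
                   m$rho0_elastin, m$rho0_collagen_per_family, layer)
  }
  materials <- list(media = lay(cfg$materials$media, "media"),
                    adventitia = lay(cfg$materials$adventitia, "adventitia"))
  d <- cfg$deposition
  deposition <- deposition_spec(d$collagen_deposition_stretch,
                                d$elastin_axial_deposition_stretch,
                                mmhg_to_mpa(d$diastolic_pressure_mmHg),
                                d$axial_stretch)
  s <- cfg$schedule
  schedule <- schedule_spec(s$n_steps, s$dt_days, s$report_days)
  p <- cfg$pattern
  pattern <- inflammation_pattern(p$duration, p$location,
                                  include_intact_media = p$include_intact_media)
  gp <- cfg$growth_parameters
  params <- growth_parameters(gp$k_sigma, gp$k_gplus_c, gp$k_gminus_c,
                              gp$k_gminus_e, gp$delta,
                              beta = if (p$duration == "transient") gp$beta else NULL,
                              T_c = gp$T_c_days)
  cr <- cfg$clinical_ranges
  ranges <- clinical_ranges(cr$acute, cr$subacute, cr$chronic)
  list(geometry = geometry, materials = materials, deposition = deposition,
       schedule = schedule, pattern = pattern, params = params,
       ranges = ranges)
}

#' Write a configuration to YAML
#'
#' @param cfg A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# Hash of the normalized configuration, embedded in outputs for provenance.
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' Command-line entry point
#'
#' Subcommands:
#' \describe{
#'   \item{simulate}{`simulate [--config cfg.yaml] --out DIR` — run one
#'     simulation with the configured growth parameters; writes
#'     `timeseries.csv`, `outcome.csv` and `result.json`.}
#'   \item{study}{`study [--config cfg.yaml] [--pattern transient|permanent]
#'     [--location full|local] [--n N] [--seed S] --out DIR` — Latin
#'     hypercube study; writes `samples.csv`, `outcomes.csv`,
#'     `summary.json`.}
#'   \item{summarize}{`summarize --outcomes outcomes.csv --out DIR` —
#'     re-aggregate an existing outcomes table.}
#' }
#' Every output carries the configuration hash and seed for provenance.
#'
#' @param argv Character vector of arguments (e.g. `commandArgs(TRUE)`).
#' @return Integer exit code, 0 on success.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: dissectgr <simulate|study|summarize> [options]",
    "  simulate  [--config cfg.yaml] --out DIR",
    "  study     [--config cfg.yaml] [--pattern P] [--location L] [--n N] [--seed S] --out DIR",
    "  summarize --outcomes outcomes.csv --out DIR",
    sep = "\n")
  if (!length(argv)) { message(usage); return(1L) }
  cmd <- argv[1]
  opts <- parse_cli_options(argv[-1])
  if (is.character(opts)) { message(opts, "\n", usage); return(1L) }

  tryCatch({
    switch(cmd,
      simulate = cli_simulate(opts),
      study = cli_study(opts),
      summarize = cli_summarize(opts),
      { message("unknown command '", cmd, "'\n", usage); return(1L) })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
}

parse_cli_options <- function(args) {
  known <- c("--config", "--out", "--pattern", "--location", "--n", "--seed",
             "--outcomes")
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    key <- args[i]
    if (!key %in% known) return(paste0("unknown flag '", key, "'"))
    if (i == length(args)) return(paste0("missing value for '", key, "'"))
    opts[[sub("^--", "", key)]] <- args[i + 1]
    i <- i + 2
  }
  opts
}

cli_load <- function(opts) {
  if (!is.null(opts$config)) load_config(opts$config) else default_config()
}

cli_simulate <- function(opts) {
  if (is.null(opts$out)) stop("simulate: --out DIR is required")
  cfg <- cli_load(opts)
  obj <- config_objects(cfg)
  res <- run_simulation(obj$params, obj$pattern, geometry = obj$geometry,
                        materials = obj$materials, deposition = obj$deposition,
                        schedule = obj$schedule)
  oc <- outcome_record(res, obj$ranges)
  dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
  prov <- list(config_hash = config_hash(cfg), seed = cfg$study$seed)
  utils::write.csv(res$timeseries, file.path(opts$out, "timeseries.csv"),
                   row.names = FALSE)
  utils::write.csv(oc, file.path(opts$out, "outcome.csv"), row.names = FALSE)
  jsonlite::write_json(
    c(prov, list(converged = res$converged,
                 n_steps_completed = res$n_steps_completed,
                 outcome = as.list(oc))),
    file.path(opts$out, "result.json"), auto_unbox = TRUE, digits = NA)
  message(sprintf("simulate: converged=%s, outputs in %s", res$converged,
                  opts$out))
  0L
}

cli_study <- function(opts) {
  if (is.null(opts$out)) stop("study: --out DIR is required")
  cfg <- cli_load(opts)
  if (!is.null(opts$pattern)) cfg$pattern$duration <- opts$pattern
  if (!is.null(opts$location)) cfg$pattern$location <- opts$location
  if (!is.null(opts$n)) cfg$study$n <- as.integer(opts$n)
  if (!is.null(opts$seed)) cfg$study$seed <- as.integer(opts$seed)
  obj <- config_objects(cfg)
  samples <- latin_hypercube(cfg$study$n, cfg$pattern$duration,
                             seed = cfg$study$seed)
  st <- run_study(samples, cfg$pattern$location, geometry = obj$geometry,
                  materials = obj$materials, deposition = obj$deposition,
                  schedule = obj$schedule, ranges = obj$ranges,
                  include_intact_media = cfg$pattern$include_intact_media)
  dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
  prov <- list(config_hash = config_hash(cfg), seed = cfg$study$seed)
  utils::write.csv(as.data.frame(samples), file.path(opts$out, "samples.csv"),
                   row.names = FALSE)
  utils::write.csv(st$outcomes, file.path(opts$out, "outcomes.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    c(prov, list(duration = st$duration, location = st$location,
                 n = nrow(st$outcomes), n_converged = st$n_converged,
                 n_clinical = st$n_clinical, success_rate = st$success_rate,
                 reduction_converged = st$reduction_converged,
                 reduction_clinical = st$reduction_clinical)),
    file.path(opts$out, "summary.json"), auto_unbox = TRUE, digits = NA)
  message(sprintf("study: %d/%d converged, outputs in %s", st$n_converged,
                  nrow(st$outcomes), opts$out))
  0L
}

cli_summarize <- function(opts) {
  if (is.null(opts$outcomes)) stop("summarize: --outcomes FILE is required")
  if (is.null(opts$out)) stop("summarize: --out DIR is required")
  oc <- utils::read.csv(opts$outcomes)
  if (nrow(oc) == 0L) {
    message("summarize: no samples in ", opts$outcomes)
    return(1L)
  }
  n_conv <- sum(oc$converged)
  n_clin <- sum(oc$converged & oc$in_clinical_range)
  dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(n = nrow(oc), n_converged = n_conv, n_clinical = n_clin,
         success_rate = n_conv / nrow(oc)),
    file.path(opts$out, "summary.json"), auto_unbox = TRUE, digits = NA)
  message(sprintf("summarize: %d/%d converged", n_conv, nrow(oc)))
  0L
}
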