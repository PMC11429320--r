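SCENARIO_IDS <- c("S1_healthy_iv", "S2_ibd_adult_iv", "S3_sc_switch_adult",
                  "S4_pediatric_iv", "S5_pediatric_sc", "S6_population_dose")

#' Scenario configuration with defaults
#'
#' Builds a fully-defaulted configuration for one exploration scenario.
#' Any field can be overridden through the nested lists; unknown fields
#' are rejected.  The same structure is produced by
#' [load_scenario_config()] from a YAML or JSON file.
#'
#' @param scenario One of `S1_healthy_iv`, `S2_ibd_adult_iv`,
#'   `S3_sc_switch_adult`, `S4_pediatric_iv`, `S5_pediatric_sc`,
#'   `S6_population_dose`.
#' @param individual Overrides for `age`, `body_weight`, `disease_state`.
#' @param regimen Overrides for `dose_per_kg`, `sc_dose`, `switch_week`,
#'   `interval_weeks`, `horizon_weeks`, `single_dose`.
#' @param simulation Overrides for `end_time_weeks`, `rtol`, `atol`.
#' @param metrics Overrides for `trough_weeks`,
#'   `maintenance_from_week`, `steady_state_window_weeks`.
#' @param population Overrides for `bands`, `n_per_band`, `age_range`,
#'   `weight_cv` (S6).
#' @param dose_search Overrides for `candidates`, `target_window`,
#'   `rule` (S6).
#' @param seed Integer seed (S6 population sampling).
#' @return An object of class `scenario_config`.
#' @export
#' @examples
#' scenario_config("S2_ibd_adult_iv")$regimen$horizon_weeks
scenario_config <- function(scenario, individual = list(),
                            regimen = list(), simulation = list(),
                            metrics = list(), population = list(),
                            dose_search = list(), seed = 1L) {
  if (!scenario %in% SCENARIO_IDS)
    stop("unknown scenario '", scenario, "'; expected one of: ",
         paste(SCENARIO_IDS, collapse = ", "), call. = FALSE)
  def <- scenario_defaults(scenario)
  cfg <- list(scenario = scenario,
              individual = merge_cfg(def$individual, individual,
                                     "individual"),
              regimen = merge_cfg(def$regimen, regimen, "regimen"),
              simulation = merge_cfg(def$simulation, simulation,
                                     "simulation"),
              metrics = merge_cfg(def$metrics, metrics, "metrics"),
              population = merge_cfg(def$population, population,
                                     "population"),
              dose_search = merge_cfg(def$dose_search, dose_search,
                                      "dose_search"),
              seed = as.integer(seed))
  validate_scenario_config(cfg)
  structure(cfg, class = "scenario_config")
}

scenario_defaults <- function(scenario) {
  ind <- switch(scenario,
    S1_healthy_iv = list(age = 30, body_weight = 70,
                         disease_state = "healthy"),
    S2_ibd_adult_iv = ,
    S3_sc_switch_adult = list(age = 40, body_weight = 70,
                              disease_state = "ibd"),
    S4_pediatric_iv = ,
    S5_pediatric_sc = list(age = 14, body_weight = 60,
                           disease_state = "ibd"),
    S6_population_dose = list(age = NA, body_weight = NA,
                              disease_state = "ibd"))
  reg <- list(dose_per_kg = 5, sc_dose = 120, switch_week = 6,
              interval_weeks = 2, horizon_weeks = 30, single_dose = FALSE)
  sim <- list(end_time_weeks = 54, rtol = 1e-8, atol = 1e-10)
  met <- list(trough_weeks = c(14, 22, 30), maintenance_from_week = 7,
              steady_state_window_weeks = c(22, 30))
  if (scenario == "S1_healthy_iv") {
    reg$single_dose <- TRUE
    reg$horizon_weeks <- 6
    sim$end_time_weeks <- 30
    met$trough_weeks <- numeric(0)
  }
  if (scenario %in% c("S3_sc_switch_adult", "S5_pediatric_sc")) {
    sim$end_time_weeks <- 60   # washout past the last SC dose
    met$trough_weeks <- c(8, 22, 30)
  }
  if (scenario == "S5_pediatric_sc") sim$end_time_weeks <- 30
  pop <- list(bands = list(c(20, 30), c(30, 45), c(45, 70)),
              n_per_band = 50, age_range = c(6, 18), weight_cv = 0.15)
  ds <- list(candidates = c(20, 40, 80, 120), target_window = c(11, 20),
             rule = "interval")
  list(individual = ind, regimen = reg, simulation = sim, metrics = met,
       population = pop, dose_search = ds)
}

merge_cfg <- function(defaults, override, where) {
  if (length(override) == 0L) return(defaults)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown))
    stop("unknown ", where, " field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  defaults[names(override)] <- override
  defaults
}

validate_scenario_config <- function(cfg) {
  errs <- character(0)
  ind <- cfg$individual
  if (cfg$scenario != "S6_population_dose") {
    if (!is.na(ind$body_weight) &&
        (ind$body_weight < 3 || ind$body_weight > 250))
      errs <- c(errs, "individual$body_weight outside [3, 250] kg")
    if (!is.na(ind$age) && (ind$age < 0 || ind$age > 120))
      errs <- c(errs, "individual$age outside [0, 120] years")
    if (!ind$disease_state %in% c("healthy", "ibd"))
      errs <- c(errs, "individual$disease_state must be healthy or ibd")
  }
  rg <- cfg$regimen
  if (rg$dose_per_kg <= 0) errs <- c(errs, "regimen$dose_per_kg must be > 0")
  if (rg$sc_dose <= 0) errs <- c(errs, "regimen$sc_dose must be > 0")
  if (rg$switch_week < 2) errs <- c(errs, "regimen$switch_week before week 2")
  if (rg$horizon_weeks < 6) errs <- c(errs, "regimen$horizon_weeks < 6")
  sim <- cfg$simulation
  if (sim$end_time_weeks * WEEK_H < rg$horizon_weeks * WEEK_H - 1e-9)
    errs <- c(errs, "simulation$end_time_weeks shorter than the regimen")
  if (sim$rtol <= 0 || sim$atol <= 0)
    errs <- c(errs, "solver tolerances must be positive")
  if (cfg$scenario == "S6_population_dose") {
    pop <- cfg$population
    if (pop$n_per_band < 1) errs <- c(errs, "population$n_per_band < 1")
    for (b in pop$bands)
      if (length(b) != 2L || b[1] >= b[2])
        errs <- c(errs, "population$bands entries must be (min, max) kg")
    ds <- cfg$dose_search
    if (any(ds$candidates <= 0)) errs <- c(errs, "dose candidates must be > 0")
    if (!ds$rule %in% c("interval", "median"))
      errs <- c(errs, "dose_search$rule must be 'interval' or 'median'")
  }
  if (length(errs))
    stop("invalid scenario configuration:\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  invisible(cfg)
}

#' Load and validate a scenario configuration file
#'
#' Reads YAML (`.yml`/`.yaml`) or JSON, injects the scenario defaults
#' (published parameter values, standard regimen layout, solver
#' tolerances) and runs all cross-field checks.  Unknown fields and
#' invalid values raise a validation error listing every violation.
#'
#' @param path Path to the configuration file.
#' @return A `scenario_config` object.
#' @export
load_scenario_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path,
                               call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$scenario)) stop("configuration lacks a 'scenario' field",
                                  call. = FALSE)
  known <- c("scenario", "individual", "regimen", "simulation", "metrics",
             "population", "dose_search", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown top-level field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(raw$population$bands))
    raw$population$bands <- lapply(seq_len(NROW(raw$population$bands)),
                                   function(i) {
      b <- raw$population$bands
      if (is.matrix(b)) as.numeric(b[i, ]) else as.numeric(b[[i]])
    })
  scenario_config(raw$scenario,
                  individual = as_cfg_list(raw$individual),
                  regimen = as_cfg_list(raw$regimen),
                  simulation = as_cfg_list(raw$simulation),
                  metrics = as_cfg_list(raw$metrics),
                  population = as_cfg_list(raw$population),
                  dose_search = as_cfg_list(raw$dose_search),
                  seed = if (is.null(raw$seed)) 1L else raw$seed)
}

as_cfg_list <- function(x) if (is.null(x)) list() else as.list(x)

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Scenario configuration '%s' (seed %d)\n", x$scenario, x$seed))
  if (x$scenario == "S6_population_dose") {
    cat(sprintf("  %d bands x %d subjects; candidates %s mg; window %g-%g mg/L (%s)\n",
                length(x$population$bands), x$population$n_per_band,
                paste(x$dose_search$candidates, collapse = "/"),
                x$dose_search$target_window[1], x$dose_search$target_window[2],
                x$dose_search$rule))
  } else {
    cat(sprintf("  %g y, %g kg, %s; horizon %g weeks, simulated to week %g\n",
                x$individual$age, x$individual$body_weight,
                x$individual$disease_state, x$regimen$horizon_weeks,
                x$simulation$end_time_weeks))
  }
  invisible(x)
}

#' Write a run manifest
#'
#' Records software version, configuration hash, seed, solver
#' tolerances, calibration file hash and a timestamp next to the
#' outputs of a run, so that deterministic scenarios can be reproduced
#' byte-for-byte from the archive.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A `scenario_config`.
#' @param calibration_path Path of the calibration file to hash;
#'   defaults to the shipped calibration.
#' @return The manifest path, invisibly.
#' @export
write_run_manifest <- function(out_dir, config, calibration_path = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(calibration_path))
    calibration_path <- system.file("extdata", "calibration.json",
                                    package = "ifxpbpk")
  cfg_file <- tempfile(fileext = ".json")
  on.exit(unlink(cfg_file))
  jsonlite::write_json(unclass(config), cfg_file, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  manifest <- list(
    package = "ifxpbpk",
    version = as.character(utils::packageVersion("ifxpbpk")),
    scenario = config$scenario,
    seed = config$seed,
    rtol = config$simulation$rtol,
    atol = config$simulation$atol,
    config_hash = unname(tools::md5sum(cfg_file)),
    calibration_hash = if (nzchar(calibration_path) &&
                           file.exists(calibration_path))
      unname(tools::md5sum(calibration_path)) else NA,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
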