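#' Run one of the six exploration scenarios
#'
#' The package's exploration arms, from model qualification to the
#' population dose suggestion:
#'
#' * `S1_healthy_iv` — healthy 70 kg adult, single 5 mg/kg 2-h infusion.
#' * `S2_ibd_adult_iv` — 70 kg IBD adult, 5 mg/kg induction (weeks 0, 2,
#'   6) and q8w maintenance.
#' * `S3_sc_switch_adult` — IBD adult, IV induction then switch at week 6
#'   to flat-fixed subcutaneous dosing every 2 weeks.
#' * `S4_pediatric_iv` — 14-year-old, 60 kg IBD patient, 5 mg/kg IV.
#' * `S5_pediatric_sc` — same child, switch to 120 mg subcutaneous.
#' * `S6_population_dose` — stratified pediatric population dose search
#'   (see [suggest_dose()]).
#'
#' @param config A scenario configuration from [scenario_config()] or
#'   [load_scenario_config()].
#' @param calibration Calibration object (defaults to the shipped one).
#' @param out_dir Optional output directory: profiles CSV, metrics CSV/
#'   JSON, regimen CSV and a run manifest are written there.
#' @return A list of class `scenario_result` with elements `config`,
#'   `profile` (or `search` for S6), `metrics`, and for S6 the
#'   [suggest_dose()] results per band.
#' @export
#' @examples
#' \donttest{
#' res <- run_scenario(scenario_config("S1_healthy_iv"))
#' res$metrics$cl
#' }
run_scenario <- function(config, calibration = read_calibration(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(calibration))
    stop("scenario runs require a calibration (see ",
         "calibrate_reference_adult)", call. = FALSE)
  id <- config$scenario
  res <- switch(
    id,
    S1_healthy_iv = ,
    S2_ibd_adult_iv = ,
    S4_pediatric_iv = run_iv_scenario(config, calibration),
    S3_sc_switch_adult = ,
    S5_pediatric_sc = run_sc_scenario(config, calibration),
    S6_population_dose = run_dose_search_scenario(config, calibration),
    stop("unknown scenario id '", id, "'", call. = FALSE)
  )
  res$config <- config
  class(res) <- "scenario_result"
  if (!is.null(out_dir)) write_scenario_outputs(res, out_dir)
  res
}

build_scenario_individual <- function(config) {
  ind <- config$individual
  virtual_individual(ind$age, ind$body_weight, ind$disease_state,
                     id = paste0(config$scenario, "_subject"))
}

run_iv_scenario <- function(config, calibration) {
  ind <- build_scenario_individual(config)
  mod <- pbpk_model(ind, drug_parameters(), system_parameters(), calibration)
  rg <- config$regimen
  single <- isTRUE(rg$single_dose)
  regimen <- iv_standard(ind$body_weight, rg$dose_per_kg, rg$horizon_weeks)
  if (single) regimen$events <- regimen$events[1, , drop = FALSE]
  end_time <- config$simulation$end_time_weeks * WEEK_H
  prof <- simulate(mod, regimen = regimen, end_time = end_time,
                   rtol = config$simulation$rtol,
                   atol = config$simulation$atol)
  dose <- if (single) regimen$events$amount[1] else NULL
  metrics <- nca(prof, dose = dose,
                 trough_weeks = config$metrics$trough_weeks)
  if (!single) {
    # clearance from a companion single-dose run (dose / AUC_inf)
    reg1 <- regimen; reg1$events <- reg1$events[1, , drop = FALSE]
    p1 <- simulate(mod, regimen = reg1, end_time = 5000)
    m1 <- nca(p1, dose = reg1$events$amount[1])
    metrics$cl <- m1$cl
    metrics$auc_inf_single <- m1$auc_inf
    metrics$vz_per_kg <- m1$vz_per_kg
    # maintenance-phase Cmax: after the week-6 induction peak has passed
    mw <- config$metrics$maintenance_from_week
    metrics$cmax_maintenance <- max(prof$conc[prof$time > mw * WEEK_H])
  }
  list(profile = prof, metrics = metrics, model = mod)
}

run_sc_scenario <- function(config, calibration) {
  ind <- build_scenario_individual(config)
  mod <- pbpk_model(ind, drug_parameters(), system_parameters(), calibration)
  rg <- config$regimen
  regimen <- sc_switch(ind$body_weight, rg$sc_dose, rg$switch_week,
                       rg$interval_weeks, rg$horizon_weeks, rg$dose_per_kg)
  end_time <- config$simulation$end_time_weeks * WEEK_H
  prof <- simulate(mod, regimen = regimen, end_time = end_time,
                   rtol = config$simulation$rtol,
                   atol = config$simulation$atol)
  metrics <- nca(prof, trough_weeks = config$metrics$trough_weeks)
  sw <- config$metrics$steady_state_window_weeks
  ss <- prof[prof$time >= sw[1] * WEEK_H & prof$time <= sw[2] * WEEK_H, ]
  metrics$cmax_ss <- max(ss$conc)
  list(profile = prof, metrics = metrics, model = mod)
}

run_dose_search_scenario <- function(config, calibration) {
  ds <- config$dose_search
  bands <- config$population$bands
  out <- vector("list", length(bands))
  for (b in seq_along(bands)) {
    spec <- population_spec(
      n_per_band = config$population$n_per_band,
      age_range = config$population$age_range,
      weight_band = bands[[b]],
      weight_cv = config$population$weight_cv,
      seed = config$seed + b - 1L)
    out[[b]] <- suggest_dose(spec, candidates = ds$candidates,
                             target_window = ds$target_window,
                             calibration = calibration,
                             rule = ds$rule,
                             switch_week = config$regimen$switch_week,
                             interval_weeks = config$regimen$interval_weeks,
                             horizon_weeks = config$regimen$horizon_weeks)
  }
  names(out) <- vapply(bands, function(b) sprintf("%g-%g kg", b[1], b[2]), "")
  sel <- vapply(out, function(r) r$selected_dose, numeric(1))
  list(search = out, metrics = list(selected_doses = sel))
}

#' Trough-matched subcutaneous dose suggestion for a weight band
#'
#' Simulates every candidate flat subcutaneous dose over a virtual
#' population of one weight band (IV induction at weeks 0 and 2, switch
#' at `switch_week`), reads the steady-state pre-dose trough at the
#' latest dose event at or beyond week 22, and selects the smallest
#' candidate whose trough distribution is comparable to the adult
#' post-switch exposure.
#'
#' Comparability (`rule`):
#' * `"interval"` (default): both the median trough and the 5th
#'   percentile reach the window's lower bound, i.e. the whole
#'   prediction interval is covered and no part of the population is
#'   underexposed relative to the adult reference.  Troughs above the
#'   window are tolerated (moderately higher pediatric troughs have not
#'   been flagged as a safety concern).
#' * `"median"`: the median alone must lie inside the window.
#'
#' @param population A [population_spec()] or a ready-made population
#'   from [sample_population()].
#' @param candidates Ascending candidate doses, mg.
#' @param target_window Adult reference trough window, mg/L.
#' @param calibration Calibration object.
#' @param rule Comparability rule (see above).
#' @param switch_week,interval_weeks,horizon_weeks SC regimen layout.
#' @param drug,system Parameter objects.
#' @return An object of class `dose_search_result`: per-candidate median
#'   and 5th/95th percentile troughs, the selected dose (`NA` if none
#'   qualifies), and the population used.
#' @export
suggest_dose <- function(population, candidates = c(20, 40, 60, 80, 100,
                                                    120, 160, 240),
                         target_window = c(11, 20),
                         calibration = read_calibration(),
                         rule = c("interval", "median"),
                         switch_week = 6, interval_weeks = 2,
                         horizon_weeks = 30,
                         drug = drug_parameters(),
                         system = system_parameters()) {
  rule <- match.arg(rule)
  if (is.unsorted(candidates, strictly = TRUE))
    stop("'candidates' must be strictly ascending", call. = FALSE)
  stopifnot(length(target_window) == 2L, target_window[1] < target_window[2])
  pop <- if (inherits(population, "population_spec"))
    sample_population(population) else population
  # steady-state trough: latest pre-dose time at or beyond week 22
  sc_weeks <- seq(switch_week, horizon_weeks, by = interval_weeks)
  trough_week <- max(sc_weeks[sc_weeks >= 22])
  if (!is.finite(trough_week))
    stop("horizon too short: no SC dose at or beyond week 22", call. = FALSE)
  end_time <- horizon_weeks * WEEK_H
  grid <- sc_trough_grid(end_time)

  models <- lapply(pop, function(ind)
    pbpk_model(ind, drug, system, calibration))
  stats_tab <- data.frame(dose = candidates, median = NA_real_,
                          q05 = NA_real_, q95 = NA_real_,
                          qualifies = FALSE)
  troughs <- matrix(NA_real_, nrow = length(pop), ncol = length(candidates))
  for (d in seq_along(candidates)) {
    for (i in seq_along(pop)) {
      reg <- sc_switch(pop[[i]]$body_weight, candidates[d], switch_week,
                       interval_weeks, horizon_weeks)
      prof <- simulate(models[[i]], regimen = reg, end_time = end_time,
                       t_grid = grid)
      troughs[i, d] <- trough_at_weeks(prof, trough_week)$conc
    }
    qs <- stats::quantile(troughs[, d], c(0.05, 0.5, 0.95), names = FALSE)
    stats_tab$q05[d] <- qs[1]
    stats_tab$median[d] <- qs[2]
    stats_tab$q95[d] <- qs[3]
    stats_tab$qualifies[d] <- if (rule == "median")
      qs[2] >= target_window[1] && qs[2] <= target_window[2]
    else  # coverage: no underexposure anywhere in the prediction interval
      qs[2] >= target_window[1] && qs[1] >= target_window[1]
  }
  sel <- stats_tab$dose[stats_tab$qualifies]
  structure(list(
    weight_band = attr(pop, "spec")$weight_band,
    candidates = stats_tab,
    troughs = troughs,
    trough_week = trough_week,
    selected_dose = if (length(sel)) min(sel) else NA_real_,
    target_window = target_window,
    rule = rule,
    population = pop
  ), class = "dose_search_result")
}

# coarse grid for population trough runs: 8 h spacing plus exact
# pre-dose samples (added by default_grid machinery via t_grid union)
sc_trough_grid <- function(end_time) {
  g <- seq(0, end_time, by = 8)
  pre <- seq(WEEK_H, end_time, by = WEEK_H) - 1e-6
  sort(unique(c(g, pre, end_time)))
}

#' @export
print.dose_search_result <- function(x, ...) {
  cat(sprintf("Dose search, band %g-%g kg (trough at week %g, window %g-%g mg/L, rule '%s')\n",
              x$weight_band[1], x$weight_band[2], x$trough_week,
              x$target_window[1], x$target_window[2], x$rule))
  print(x$candidates, row.names = FALSE, digits = 3)
  cat(if (is.na(x$selected_dose)) "  no candidate qualifies\n" else
    sprintf("  selected dose: %g mg\n", x$selected_dose))
  invisible(x)
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Scenario %s\n", x$config$scenario))
  if (!is.null(x$search)) {
    for (r in x$search) print(r)
  } else {
    print(x$metrics)
  }
  invisible(x)
}

write_scenario_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  id <- res$config$scenario
  if (!is.null(res$profile)) {
    write_profile_csv(res$profile, file.path(out_dir,
                                             paste0(id, "_profile.csv")))
    write_regimen_csv(attr(res$profile, "regimen"),
                      file.path(out_dir, paste0(id, "_regimen.csv")))
    mdf <- as.data.frame(res$metrics)
    mdf <- cbind(individual = attr(res$profile, "individual")$id, mdf)
    utils::write.csv(mdf, file.path(out_dir, paste0(id, "_metrics.csv")),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(unclass(res$metrics),
                         file.path(out_dir, paste0(id, "_metrics.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  } else {
    for (nm in names(res$search)) {
      r <- res$search[[nm]]
      utils::write.csv(r$candidates,
                       file.path(out_dir, sprintf("%s_%s_candidates.csv", id,
                                                  gsub("[^0-9a-zA-Z-]", "",
                                                       nm))),
                       row.names = FALSE, quote = FALSE)
    }
    jsonlite::write_json(res$metrics$selected_doses,
                         file.path(out_dir, paste0(id, "_selected_doses.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  write_run_manifest(out_dir, res$config)
  invisible(out_dir)
}
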