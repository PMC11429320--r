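#' Calibrate the two unpublished disposition constants
#'
#' The published parameter table pins every endosomal sorting rate but
#' not the total endosomal FcRn concentration nor the plasma to
#' interstitial exchange constant.  These two constants are tuned once
#' so that the healthy 70 kg reference adult, after a single 5 mg/kg
#' (350 mg) 2-h intravenous infusion, reproduces the reference simulated
#' exposure metrics (AUC extrapolated to infinity and Cmax).  Every
#' other scenario then runs without further tuning; only the published
#' disease switch of the endosomal clearance and the individual's
#' biometrics change.
#'
#' @param target_auc_inf Target AUC extrapolated to infinity, mg*h/L
#'   (fixes the systemic clearance, dose / AUC).
#' @param target_cmax Target maximum concentration, mg/L.
#' @param target_vz_per_kg Target apparent terminal volume of
#'   distribution, L/kg.
#' @param start Named starting values
#'   `c(fcrn_endo_conc, k_dist, v_endo_ref)`.
#' @param drug,system Parameter objects (the calibrated fields of
#'   `system` are ignored).
#' @param sim_end Washout horizon of the calibration simulation, h.
#' @param reltol Convergence tolerance of the optimizer.
#' @return An object of class `pbpk_calibration`: a list with
#'   `fcrn_endo_conc` (µmol/L), `k_dist` (1/h), `v_endo_ref` (L), the
#'   achieved metrics and their relative residuals.
#' @export
calibrate_reference_adult <- function(target_auc_inf = 40311,
                                      target_cmax = 110,
                                      target_vz_per_kg = 0.07,
                                      start = c(fcrn_endo_conc = 100,
                                                k_dist = 0.08,
                                                v_endo_ref = 0.02),
                                      drug = drug_parameters(),
                                      system = system_parameters(),
                                      sim_end = 5000,
                                      reltol = 1e-10) {
  model_for <- function(fcrn, kd, ve_ref) {
    adult <- virtual_individual(30, 70, "healthy", id = "reference_adult",
                                v_endo_ref = ve_ref,
                                f_endo = system$f_endo)
    sys <- system
    sys$fcrn_endo_conc <- fcrn
    sys$k_dist <- kd
    pbpk_model(adult, drug, sys, calibration = NULL)
  }
  single_dose <- function() {
    reg <- iv_standard(70, 5, 6)
    reg$events <- reg$events[1, , drop = FALSE]
    reg
  }
  # fast, smooth objective: exact AUC/terminal slope from the linearised
  # rate matrix; Cmax from a short simulation of the 2-h infusion
  fast_metrics <- function(fcrn, kd, ve_ref) {
    mod <- model_for(fcrn, kd, ve_ref)
    lm0 <- linear_iv_metrics(mod, 350)
    reg <- single_dose()
    prof <- simulate(mod, regimen = reg, end_time = 3,
                     t_grid = seq(0, 3, by = 0.05))
    c(auc_inf = lm0[["auc_inf"]], cmax = max(prof$conc),
      vz_per_kg = lm0[["cl"]] / lm0[["lambda_z"]] / 70)
  }
  obj <- function(lp) {
    m <- fast_metrics(exp(lp[1]), exp(lp[2]), exp(lp[3]))
    (m[["auc_inf"]] / target_auc_inf - 1)^2 +
      (m[["cmax"]] / target_cmax - 1)^2 +
      (m[["vz_per_kg"]] / target_vz_per_kg - 1)^2
  }
  fit <- stats::optim(log(start), obj, method = "Nelder-Mead",
                      control = list(reltol = reltol, maxit = 2000))
  fcrn <- exp(fit$par[[1]]); kd <- exp(fit$par[[2]])
  ve_ref <- exp(fit$par[[3]])
  # achieved metrics from the full nonlinear simulation + NCA
  mod <- model_for(fcrn, kd, ve_ref)
  prof <- simulate(mod, regimen = single_dose(), end_time = sim_end)
  m <- nca(prof, dose = 350)
  ach <- c(auc_inf = m$auc_inf, cmax = m$cmax, cl = m$cl,
           vz_per_kg = m$vz_per_kg, t_half_days = m$t_half_days)
  structure(list(
    fcrn_endo_conc = fcrn,
    k_dist = kd,
    v_endo_ref = ve_ref,
    targets = c(auc_inf = target_auc_inf, cmax = target_cmax,
                vz_per_kg = target_vz_per_kg),
    achieved = ach,
    residuals = c(auc_inf = ach[["auc_inf"]] / target_auc_inf - 1,
                  cmax = ach[["cmax"]] / target_cmax - 1,
                  vz_per_kg = ach[["vz_per_kg"]] / target_vz_per_kg - 1),
    objective = fit$value, convergence = fit$convergence
  ), class = "pbpk_calibration")
}

#' @export
print.pbpk_calibration <- function(x, ...) {
  cat("Reference-adult calibration\n")
  cat(sprintf("  FcRn (endosome, total): %.6g umol/L\n", x$fcrn_endo_conc))
  cat(sprintf("  k_dist                : %.6g 1/h\n", x$k_dist))
  cat(sprintf("  achieved AUC_inf %.5g mg*h/L (res %.2e), Cmax %.4g mg/L (res %.2e)\n",
              x$achieved[["auc_inf"]], x$residuals[["auc_inf"]],
              x$achieved[["cmax"]], x$residuals[["cmax"]]))
  cat(sprintf("  implied CL %.4g L/h, Vz %.3g L/kg, t1/2 %.3g d\n",
              x$achieved[["cl"]], x$achieved[["vz_per_kg"]],
              x$achieved[["t_half_days"]]))
  invisible(x)
}

#' Write a calibration to JSON
#' @param x A `pbpk_calibration`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_calibration <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a calibration from JSON
#'
#' @param path Path to a calibration JSON; defaults to the calibration
#'   shipped with the package.
#' @return A `pbpk_calibration` object.
#' @export
read_calibration <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "calibration.json", package = "ifxpbpk")
    if (path == "") stop("no shipped calibration found", call. = FALSE)
  }
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "pbpk_calibration")
}
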