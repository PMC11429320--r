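#' Specification of a synthetic trial observation set
#'
#' Synthetic stand-ins for the clinical profiles the model is qualified
#' against: a healthy-adult single-dose IV profile whose
#' non-compartmental metrics match the published trial values, an IBD
#' multiple-dose IV trough series, and a post-switch subcutaneous trough
#' series.  The reference curves are classical two-compartment models
#' (with a first-order depot for the SC series) whose micro-constants
#' are solved numerically from the target metrics; multiplicative
#' lognormal noise of a given CV is applied per sample.
#'
#' @param kind `"healthy_single_iv"`, `"ibd_multidose_iv"` or
#'   `"sc_switch_troughs"`.
#' @param cv Proportional (lognormal) noise coefficient of variation;
#'   0 gives the noise-free reference curve.
#' @param seed Integer seed for the noise draws.
#' @param times Sampling times (h); `NULL` selects the protocol schedule
#'   of the kind (rich sampling over 28 days for the single-dose trial,
#'   pre-dose troughs otherwise).
#' @param body_weight Reference body weight, kg.
#' @param dose_per_kg IV dose level, mg/kg.
#' @param sc_dose Subcutaneous dose, mg (`sc_switch_troughs`).
#' @param horizon_weeks Horizon of the multidose schedules.
#' @return An object of class `synthetic_trial_spec`.
#' @export
synthetic_trial_spec <- function(kind = c("healthy_single_iv",
                                          "ibd_multidose_iv",
                                          "sc_switch_troughs"),
                                 cv = 0.15, seed = 1L, times = NULL,
                                 body_weight = 70, dose_per_kg = 5,
                                 sc_dose = 120, horizon_weeks = 30) {
  kind <- match.arg(kind)
  if (cv < 0) stop("'cv' must be non-negative", call. = FALSE)
  structure(list(kind = kind, cv = cv, seed = as.integer(seed),
                 times = times, body_weight = body_weight,
                 dose_per_kg = dose_per_kg, sc_dose = sc_dose,
                 horizon_weeks = horizon_weeks),
            class = "synthetic_trial_spec")
}

# two-compartment concentration after a zero-order infusion (single dose)
conc_2cpt_inf <- function(t, dose, t_inf, v1, k10, k12, k21) {
  s <- k10 + k12 + k21
  p <- k10 * k21
  l1 <- (s + sqrt(s^2 - 4 * p)) / 2
  l2 <- (s - sqrt(s^2 - 4 * p)) / 2
  a1 <- (l1 - k21) / (l1 - l2)
  a2 <- (k21 - l2) / (l1 - l2)
  r0 <- dose / t_inf
  during <- function(tt) r0 / v1 * (a1 * (1 - exp(-l1 * tt)) / l1 +
                                      a2 * (1 - exp(-l2 * tt)) / l2)
  after <- function(tt) r0 / v1 *
    (a1 * (1 - exp(-l1 * t_inf)) * exp(-l1 * (tt - t_inf)) / l1 +
       a2 * (1 - exp(-l2 * t_inf)) * exp(-l2 * (tt - t_inf)) / l2)
  ifelse(t <= 0, 0, ifelse(t <= t_inf, during(pmax(t, 0)), after(t)))
}

lambda_z_2cpt <- function(k10, k12, k21) {
  s <- k10 + k12 + k21
  (s - sqrt(s^2 - 4 * k10 * k21)) / 2
}

# solve (v1, k21) so the two-compartment curve matches the target
# terminal slope and end-of-infusion Cmax; CL fixes k10 = CL/v1 (and with
# it the AUC), the slow distribution constant k12 is a convention
solve_2cpt <- function(dose, t_inf, cl, lambda_z_target, cmax_target,
                       k12 = 0.02) {
  k21_for <- function(v1) {
    # terminal root: lambda^2 - s lambda + k10 k21 = 0 solved for k21
    k10 <- cl / v1
    lz <- lambda_z_target
    den <- k10 - lz
    if (den <= 0) return(NA_real_)
    lz * (k10 + k12 - lz) / den
  }
  cmax_for <- function(v1) {
    k21 <- k21_for(v1)
    if (!is.finite(k21) || k21 <= lambda_z_target) return(NA_real_)
    conc_2cpt_inf(t_inf, dose, t_inf, v1, cl / v1, k12, k21)
  }
  f <- function(v1) cmax_for(v1) - cmax_target
  v_hi <- dose / cmax_target          # upper bound: no losses at all
  v_lo <- v_hi / 3
  if (!is.finite(f(v_lo)) || !is.finite(f(v_hi)) || f(v_lo) * f(v_hi) > 0)
    stop("synthetic reference infeasible: CL ", signif(cl, 3),
         " L/h, lambda_z ", signif(lambda_z_target, 3),
         " 1/h and Cmax ", cmax_target, " mg/L cannot be reconciled",
         call. = FALSE)
  v1 <- stats::uniroot(f, c(v_lo, v_hi), tol = 1e-12)$root
  k21 <- k21_for(v1)
  par <- list(v1 = v1, k10 = cl / v1, k12 = k12, k21 = k21)
  resid <- c(lambda_z = lambda_z_2cpt(par$k10, k12, k21) /
               lambda_z_target - 1,
             cmax = conc_2cpt_inf(t_inf, dose, t_inf, v1, par$k10, k12,
                                  k21) / cmax_target - 1)
  if (max(abs(resid)) > 1e-4)
    stop("synthetic reference infeasible: residuals ",
         paste(sprintf("%s=%.3g", names(resid), resid), collapse = ", "),
         call. = FALSE)
  par
}

# terminal slope matched with k12 fixed (one free constant)
solve_2cpt_lambda <- function(v1, cl, k12, lambda_z_target) {
  k10 <- cl / v1
  f <- function(k21) lambda_z_2cpt(k10, k12, k21) - lambda_z_target
  k21 <- stats::uniroot(f, c(lambda_z_target * 1.001, 10))$root
  list(v1 = v1, k10 = k10, k12 = k12, k21 = k21)
}

#' Generate a synthetic observation set
#'
#' @param spec A [synthetic_trial_spec()].
#' @return A `concentration_profile` with the reference parameters and
#'   spec stored in `metadata`; write it with [write_profile_csv()] to
#'   obtain the observations CSV consumed by [fit_parameters()].
#' @export
#' @examples
#' prof <- generate_synthetic_trial(synthetic_trial_spec(cv = 0))
#' nca(prof, dose = 350, body_weight = 70)$cl   # ~0.0092 L/h
generate_synthetic_trial <- function(spec) {
  stopifnot(inherits(spec, "synthetic_trial_spec"))
  w <- spec$body_weight
  dose <- spec$dose_per_kg * w
  if (spec$kind == "healthy_single_iv") {
    # printed trial values: AUC 38,000 mg*h/L (=> CL = dose/AUC),
    # Vd 0.09 L/kg, Cmax 121 mg/L
    cl <- dose / 38000
    lambda_z <- cl / (0.09 * w)
    par <- solve_2cpt(dose, 2, cl, lambda_z, 121)
    times <- if (is.null(spec$times))
      c(0, 1, 2, 4, 8, c(1, 3, 7, 14, 21, 28) * 24 + 2) else spec$times
    conc <- conc_2cpt_inf(times, dose, 2, par$v1, par$k10, par$k12, par$k21)
    dose_times <- 0
  } else {
    # IBD reference: CL 0.015 L/h, terminal half-life 9.5 days
    cl <- 0.015 * w / 70
    v1 <- 0.0414 * w
    lambda_z <- log(2) / (9.5 * 24)
    par <- solve_2cpt_lambda(v1, cl, 0.08, lambda_z)
    if (spec$kind == "ibd_multidose_iv") {
      wk <- c(0, 2, 6)
      if (spec$horizon_weeks >= 14)
        wk <- c(wk, seq(14, spec$horizon_weeks, by = 8))
      dose_times <- wk * WEEK_H
      times <- if (is.null(spec$times))
        c(dose_times[-1] - 1e-6, spec$horizon_weeks * WEEK_H) else spec$times
      conc <- rowSums(vapply(dose_times, function(td)
        conc_2cpt_inf(times - td, dose, 2, par$v1, par$k10, par$k12,
                      par$k21), numeric(length(times))))
    } else {
      sc_wk <- seq(6, spec$horizon_weeks, by = 2)
      dose_times <- c(0, 2 * WEEK_H, sc_wk * WEEK_H)
      times <- if (is.null(spec$times))
        c(sc_wk[-1] * WEEK_H - 1e-6, spec$horizon_weeks * WEEK_H)
      else spec$times
      iv_part <- rowSums(vapply(c(0, 2 * WEEK_H), function(td)
        conc_2cpt_inf(times - td, dose, 2, par$v1, par$k10, par$k12,
                      par$k21), numeric(length(times))))
      sc_part <- rowSums(vapply(sc_wk * WEEK_H, function(td)
        conc_2cpt_sc(times - td, 0.79 * spec$sc_dose, 0.0114, par),
        numeric(length(times))))
      conc <- iv_part + sc_part
    }
  }
  if (spec$cv > 0) {
    sdlog <- sqrt(log(1 + spec$cv^2))
    old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(spec$seed)
    conc <- conc * stats::rlnorm(length(conc), meanlog = 0, sdlog = sdlog)
  }
  prof <- concentration_profile(times, conc,
                                metadata = list(spec = spec,
                                                reference = par,
                                                dose = dose))
  attr(prof, "dose_times") <- dose_times
  prof
}

# two-compartment disposition with a first-order depot (single SC dose of
# bioavailable amount fa_dose), solved through the eigen-decomposition of
# the 3-state rate matrix
conc_2cpt_sc <- function(t, fa_dose, ka, par) {
  A <- matrix(c(-ka, 0, 0,
                ka, -(par$k10 + par$k12), par$k21,
                0, par$k12, -par$k21), nrow = 3, byrow = TRUE)
  eg <- eigen(A)
  w0 <- solve(eg$vectors, c(fa_dose, 0, 0))
  central <- function(tt) {
    if (tt <= 0) return(0)
    x <- eg$vectors %*% (w0 * exp(eg$values * tt))
    Re(x[2]) / par$v1
  }
  vapply(t, central, numeric(1))
}
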