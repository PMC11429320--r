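#' Trapezoidal area under the concentration-time curve
#'
#' Linear-up/log-down trapezoid: intervals where the concentration
#' declines and both endpoints are positive use the logarithmic
#' trapezoid, all others the linear rule.
#'
#' @param profile A `concentration_profile` (or data.frame with `time`,
#'   `conc`).
#' @param from,to Optional integration window (h); defaults to the full
#'   profile.
#' @param method `"log_linear"` (default) or `"linear"`.
#' @return AUC in mg*h/L.
#' @export
#' @examples
#' p <- concentration_profile(0:10, rep(1, 11))
#' auc_trapezoid(p)  # 10
auc_trapezoid <- function(profile, from = NULL, to = NULL,
                          method = c("log_linear", "linear")) {
  method <- match.arg(method)
  t <- profile$time; c0 <- profile$conc
  if (length(t) < 2L) stop("AUC needs at least 2 points", call. = FALSE)
  if (any(c0 < 0)) stop("concentrations must be non-negative", call. = FALSE)
  if (!is.null(from) || !is.null(to)) {
    if (is.null(from)) from <- t[1]
    if (is.null(to)) to <- t[length(t)]
    keep <- t >= from - 1e-12 & t <= to + 1e-12
    t <- t[keep]; c0 <- c0[keep]
    if (length(t) < 2L) stop("fewer than 2 points in the AUC window",
                             call. = FALSE)
  }
  dt <- diff(t); c1 <- c0[-length(c0)]; c2 <- c0[-1]
  lin <- (c1 + c2) / 2 * dt
  if (method == "log_linear") {
    logdown <- c2 < c1 & c2 > 0 & c1 > 0
    lin[logdown] <- (c1[logdown] - c2[logdown]) /
      log(c1[logdown] / c2[logdown]) * dt[logdown]
  }
  sum(lin)
}

#' Terminal slope by log-linear regression with automatic window
#'
#' Candidate windows end at the last washout sample and start at each
#' earlier sample (minimum `min_points` points); the window with the
#' best adjusted R-squared is selected.  Windows with adjusted
#' R-squared below `r2_min` are disqualified.
#'
#' @param profile A `concentration_profile` of a washout segment (all
#'   samples after the last dose), positive concentrations.
#' @param min_points Minimum points in the regression window.
#' @param r2_min Minimum adjusted R-squared for a qualifying window.
#' @return A list with `lambda_z` (1/h), `t_half_days`, `intercept`
#'   (mg/L at t = 0 of the window's time axis), `r2_adj`, `window`
#'   (time range used, h), `n_points`.
#' @export
terminal_slope <- function(profile, min_points = 3L, r2_min = 0.999) {
  t <- profile$time; c0 <- profile$conc
  keep <- c0 > 0
  t <- t[keep]; c0 <- c0[keep]
  n <- length(t)
  if (n < 5L)
    stop("terminal slope estimation needs at least 5 positive washout ",
         "samples", call. = FALSE)
  if (n > 150L) {           # dense simulated grids: thin before the search
    idx <- unique(round(seq(1L, n, length.out = 150L)))
    t <- t[idx]; c0 <- c0[idx]; n <- length(t)
  }
  lc <- log(c0)
  best <- NULL
  for (start in seq_len(n - min_points + 1L)) {
    idx <- start:n
    ti <- t[idx]; yi <- lc[idx]
    fit <- stats::lm.fit(cbind(1, ti), yi)
    slope <- fit$coefficients[2]
    if (!is.finite(slope) || slope >= 0) next
    m <- length(idx)
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((yi - mean(yi))^2)
    if (ss_tot <= 0) next
    r2 <- 1 - ss_res / ss_tot
    r2a <- 1 - (1 - r2) * (m - 1) / (m - 2)
    if (r2a < r2_min) next
    if (is.null(best) || r2a > best$r2_adj) {
      best <- list(lambda_z = -unname(slope),
                   t_half_days = log(2) / -unname(slope) / 24,
                   intercept = exp(unname(fit$coefficients[1])),
                   r2_adj = r2a, window = range(ti), n_points = m)
    }
  }
  if (is.null(best))
    stop(sprintf(paste0("no terminal window with >= %d points reached ",
                        "adjusted R^2 >= %g"), min_points, r2_min),
         call. = FALSE)
  best
}

#' Terminal half-life of a simulated or observed profile
#'
#' Convenience wrapper around [terminal_slope()]: restricts the profile
#' to the washout after the last dose (if a regimen is attached) and
#' returns the half-life in days.
#'
#' @param profile A `concentration_profile`.
#' @param after Optional start of the washout window (h); defaults to
#'   the last dose time of the attached regimen (plus its infusion), or
#'   0 if none.
#' @param ... Passed to [terminal_slope()].
#' @return Half-life in days.
#' @export
terminal_half_life <- function(profile, after = NULL, ...) {
  if (is.null(after)) {
    reg <- attr(profile, "regimen")
    after <- if (is.null(reg)) 0 else {
      last <- nrow(reg$events)
      reg$events$time[last] + max(reg$events$duration[last], 0, na.rm = TRUE)
    }
  }
  wash <- profile[profile$time > after, , drop = FALSE]
  terminal_slope(wash, ...)$t_half_days
}

#' Pre-dose trough concentrations at given weeks
#'
#' Returns the concentration immediately before the dose event at each
#' requested week (pre-dose sample convention).  Weeks without a dose
#' event are interpolated at the exact week time and flagged
#' `non_trough`.
#'
#' @param profile A `concentration_profile` with an attached regimen
#'   (from [simulate.pbpk_model()]), or any profile if `dose_times` is
#'   given.
#' @param weeks Numeric vector of weeks.
#' @param dose_times Optional dose times (h) overriding the attached
#'   regimen.
#' @return A data.frame with `week`, `conc` (mg/L) and `non_trough`.
#' @export
trough_at_weeks <- function(profile, weeks, dose_times = NULL) {
  if (is.null(dose_times)) {
    reg <- attr(profile, "regimen")
    dose_times <- if (is.null(reg)) numeric(0) else reg$events$time
  }
  out <- data.frame(week = as.numeric(weeks),
                    conc = rep(NA_real_, length(weeks)),
                    non_trough = rep(FALSE, length(weeks)))
  for (j in seq_along(weeks)) {
    tw <- weeks[j] * WEEK_H
    if (tw > max(profile$time) + 1e-9)
      stop("profile does not cover week ", weeks[j], call. = FALSE)
    has_dose <- any(abs(dose_times - tw) < 1e-6)
    if (has_dose) {
      idx <- which(profile$time < tw - 1e-12)
      if (length(idx) == 0L) stop("no sample before the dose at week ",
                                  weeks[j], call. = FALSE)
      out$conc[j] <- profile$conc[max(idx)]
    } else {
      out$conc[j] <- stats::approx(profile$time, profile$conc, xout = tw,
                                   rule = 2)$y
      out$non_trough[j] <- TRUE
    }
  }
  out
}

#' Non-compartmental exposure metrics for one profile
#'
#' Computes AUC to the last sample, AUC extrapolated to infinity
#' (single-dose profiles), Cmax/Tmax, the terminal slope, half-life,
#' clearance (`dose / AUC_inf`), and apparent volumes of distribution
#' (`Vz = CL / lambda_z`, primary; `Vss` from moment analysis of
#' single-dose IV profiles).
#'
#' @param profile A `concentration_profile`.
#' @param dose Administered dose for the clearance computation, mg
#'   (bioavailable dose for extravascular routes).
#' @param body_weight Body weight (kg) used to normalise volumes; taken
#'   from the attached individual when absent.
#' @param washout_after Start of the washout (h) for the terminal fit;
#'   defaults to the last dose of the attached regimen.
#' @param extrapolate Add `C_last / lambda_z` to obtain `auc_inf`.
#' @param trough_weeks Optional weeks at which pre-dose troughs are
#'   reported.
#' @return An object of class `pk_metrics` (a list).
#' @export
#' @examples
#' mod <- pbpk_model(virtual_individual(30, 70))
#' prof <- simulate(mod, regimen = iv_standard(70, 5, 6), end_time = 3000)
#' m <- nca(prof, dose = 350)
#' m$cl
nca <- function(profile, dose = NULL, body_weight = NULL,
                washout_after = NULL, extrapolate = TRUE,
                trough_weeks = NULL) {
  stopifnot(nrow(profile) >= 2L)
  if (is.null(body_weight)) {
    ind <- attr(profile, "individual")
    if (!is.null(ind)) body_weight <- ind$body_weight
  }
  auc_last <- auc_trapezoid(profile)
  imax <- which.max(profile$conc)
  res <- list(auc_last = auc_last, cmax = profile$conc[imax],
              tmax = profile$time[imax])
  after <- washout_after
  if (is.null(after)) {
    reg <- attr(profile, "regimen")
    after <- if (is.null(reg)) 0 else {
      last <- nrow(reg$events)
      reg$events$time[last] + max(reg$events$duration[last], 0, na.rm = TRUE)
    }
  }
  sl <- tryCatch(
    terminal_slope(profile[profile$time > after, , drop = FALSE]),
    error = function(e) NULL)
  if (!is.null(sl)) {
    res$lambda_z <- sl$lambda_z
    res$t_half_days <- sl$t_half_days
    if (extrapolate) {
      c_last <- profile$conc[nrow(profile)]
      if (c_last <= 0)
        stop("cannot extrapolate AUC: last concentration is zero",
             call. = FALSE)
      res$auc_inf <- auc_last + c_last / sl$lambda_z
    }
  }
  if (!is.null(dose) && !is.null(res$auc_inf)) {
    res$cl <- dose / res$auc_inf
    if (!is.null(res$lambda_z)) {
      res$vz <- res$cl / res$lambda_z
      if (!is.null(body_weight)) res$vz_per_kg <- res$vz / body_weight
    }
    # Vss by moment analysis (meaningful for single-dose IV profiles)
    t <- profile$time; c0 <- profile$conc
    aumc <- auc_trapezoid(concentration_profile(t, t * c0))
    if (!is.null(res$lambda_z)) {
      c_last <- c0[length(c0)]; t_last <- t[length(t)]
      aumc_inf <- aumc + c_last * t_last / res$lambda_z +
        c_last / res$lambda_z^2
      res$vss <- res$cl * aumc_inf / res$auc_inf
    }
  }
  if (!is.null(trough_weeks) && length(trough_weeks) > 0)
    res$trough <- trough_at_weeks(profile, trough_weeks)
  res$body_weight <- body_weight
  structure(res, class = "pk_metrics")
}

#' @export
print.pk_metrics <- function(x, ...) {
  cat("Non-compartmental metrics\n")
  fmt <- function(nm, v, u) if (!is.null(v))
    cat(sprintf("  %-12s %.5g %s\n", nm, v, u))
  fmt("AUC_last", x$auc_last, "mg*h/L")
  fmt("AUC_inf", x$auc_inf, "mg*h/L")
  fmt("Cmax", x$cmax, sprintf("mg/L (t = %.3g h)", x$tmax))
  fmt("t1/2", x$t_half_days, "days")
  fmt("CL", x$cl, "L/h")
  fmt("Vz", x$vz_per_kg, "L/kg")
  fmt("Vss", x$vss, "L")
  if (!is.null(x$trough)) {
    cat("  troughs:\n")
    print(x$trough, row.names = FALSE)
  }
  invisible(x)
}

#' Metrics as a tidy data.frame (`metric`, `value`, `units`)
#' @param x A `pk_metrics` object.
#' @param ... Unused.
#' @return A data.frame.
#' @export
as.data.frame.pk_metrics <- function(x, ...) {
  rows <- list(
    c("auc_last", x$auc_last, "mg*h/L"), c("auc_inf", x$auc_inf, "mg*h/L"),
    c("cmax", x$cmax, "mg/L"), c("tmax", x$tmax, "h"),
    c("lambda_z", x$lambda_z, "1/h"), c("t_half", x$t_half_days, "days"),
    c("cl", x$cl, "L/h"), c("vz", x$vz, "L"),
    c("vz_per_kg", x$vz_per_kg, "L/kg"), c("vss", x$vss, "L"))
  rows <- Filter(function(r) length(r) == 3L && !is.na(r[2]), rows)
  df <- data.frame(metric = vapply(rows, `[`, "", 1),
                   value = as.numeric(vapply(rows, `[`, "", 2)),
                   units = vapply(rows, `[`, "", 3),
                   stringsAsFactors = FALSE)
  if (!is.null(x$trough)) {
    df <- rbind(df, data.frame(
      metric = sprintf("trough_week_%g", x$trough$week),
      value = x$trough$conc, units = "mg/L", stringsAsFactors = FALSE))
  }
  df
}
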