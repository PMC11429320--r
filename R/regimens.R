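#' Dosing regimens as explicit event lists
#'
#' A regimen is an ordered table of dose events (time in hours, route,
#' nominal amount in mg, infusion duration for IV events) plus a
#' simulation horizon.  Event times are exact multiples of one week
#' (168 h) so multi-year schedules carry no floating drift.
#'
#' @param events A data.frame with columns `time` (h), `route`
#'   (`"iv_infusion"` or `"sc"`), `amount` (mg), `duration` (h; `NA` for
#'   SC events).
#' @param horizon Simulation horizon, h.
#' @param label Regimen label.
#' @return An object of class `regimen`.
#' @export
regimen <- function(events, horizon, label = "custom") {
  stopifnot(is.data.frame(events),
            all(c("time", "route", "amount", "duration") %in% names(events)))
  if (nrow(events) == 0L) stop("regimen needs at least one dose event",
                               call. = FALSE)
  if (any(events$amount <= 0)) stop("dose amounts must be positive",
                                    call. = FALSE)
  if (!all(events$route %in% c("iv_infusion", "sc")))
    stop("route must be 'iv_infusion' or 'sc'", call. = FALSE)
  iv <- events$route == "iv_infusion"
  if (any(iv & (is.na(events$duration) | events$duration <= 0)))
    stop("IV events need a positive infusion duration", call. = FALSE)
  events <- events[order(events$time), , drop = FALSE]
  rownames(events) <- NULL
  if (horizon < max(events$time))
    stop("horizon must cover all dose events", call. = FALSE)
  structure(list(label = label, events = events, horizon = horizon),
            class = "regimen")
}

WEEK_H <- 168

#' Standard intravenous induction/maintenance regimen
#'
#' 2-hour infusions of `dose_per_kg` mg/kg at weeks 0, 2 and 6
#' (induction) and then every 8 weeks (weeks 14, 22, 30, ...) up to the
#' horizon.
#'
#' @param body_weight Body weight, kg.
#' @param dose_per_kg Dose, mg/kg (default 5).
#' @param horizon_weeks Simulation horizon in weeks (>= 6).
#' @param maintenance_interval_weeks Maintenance dosing interval (default 8).
#' @param infusion_duration Infusion duration, h.
#' @return A [regimen()].
#' @export
#' @examples
#' iv_standard(70, 5, 54)$events
iv_standard <- function(body_weight, dose_per_kg = 5, horizon_weeks,
                        maintenance_interval_weeks = 8,
                        infusion_duration = 2) {
  if (body_weight <= 0) stop("'body_weight' must be positive", call. = FALSE)
  if (horizon_weeks < 6)
    stop("'horizon_weeks' must be at least 6 (induction spans weeks 0-6)",
         call. = FALSE)
  wk <- c(0, 2, 6)
  if (horizon_weeks >= 6 + maintenance_interval_weeks)
    wk <- c(wk, seq(6 + maintenance_interval_weeks, horizon_weeks,
                    by = maintenance_interval_weeks))
  amt <- dose_per_kg * body_weight
  ev <- data.frame(time = wk * WEEK_H, route = "iv_infusion", amount = amt,
                   duration = infusion_duration, stringsAsFactors = FALSE)
  regimen(ev, horizon = horizon_weeks * WEEK_H,
          label = sprintf("iv_%gmgkg_q%gw", dose_per_kg,
                          maintenance_interval_weeks))
}

#' Subcutaneous switch regimen
#'
#' IV induction (2-h infusions of `dose_per_kg` mg/kg at weeks 0 and 2),
#' then flat-fixed subcutaneous doses of `sc_dose` mg from `switch_week`
#' every `interval_weeks` up to the horizon.  SC events carry the nominal
#' dose; the bioavailability correction (F) is applied by the model at
#' administration.
#'
#' @param body_weight Body weight, kg (for the IV induction doses).
#' @param sc_dose Flat subcutaneous dose, mg.
#' @param switch_week Week of the first SC dose (default 6).
#' @param interval_weeks SC dosing interval in weeks (default 2).
#' @param horizon_weeks Simulation horizon in weeks.
#' @param dose_per_kg IV induction dose, mg/kg.
#' @param infusion_duration IV infusion duration, h.
#' @return A [regimen()].
#' @export
#' @examples
#' sc_switch(70, 120, horizon_weeks = 30)$events
sc_switch <- function(body_weight, sc_dose, switch_week = 6,
                      interval_weeks = 2, horizon_weeks,
                      dose_per_kg = 5, infusion_duration = 2) {
  if (body_weight <= 0) stop("'body_weight' must be positive", call. = FALSE)
  if (switch_week < 2)
    stop("'switch_week' must not precede the week-2 induction dose",
         call. = FALSE)
  if (horizon_weeks < switch_week)
    stop("'horizon_weeks' must reach the switch week", call. = FALSE)
  iv_wk <- c(0, 2)
  sc_wk <- seq(switch_week, horizon_weeks, by = interval_weeks)
  ev <- rbind(
    data.frame(time = iv_wk * WEEK_H, route = "iv_infusion",
               amount = dose_per_kg * body_weight,
               duration = infusion_duration, stringsAsFactors = FALSE),
    data.frame(time = sc_wk * WEEK_H, route = "sc", amount = sc_dose,
               duration = NA_real_, stringsAsFactors = FALSE)
  )
  regimen(ev, horizon = horizon_weeks * WEEK_H,
          label = sprintf("sc_switch_%gmg_q%gw", sc_dose, interval_weeks))
}

#' @export
print.regimen <- function(x, ...) {
  n_iv <- sum(x$events$route == "iv_infusion")
  n_sc <- sum(x$events$route == "sc")
  cat(sprintf("Regimen '%s': %d IV + %d SC events, horizon %.0f weeks\n",
              x$label, n_iv, n_sc, x$horizon / WEEK_H))
  print(utils::head(x$events, 10))
  if (nrow(x$events) > 10) cat("  ...\n")
  invisible(x)
}

#' @export
as.data.frame.regimen <- function(x, ...) {
  data.frame(time_h = x$events$time, route = x$events$route,
             amount_mg = x$events$amount, duration_h = x$events$duration,
             stringsAsFactors = FALSE)
}

#' Write a regimen to CSV (`time_h, route, amount_mg, duration_h`)
#' @param x A [regimen()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_regimen_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
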