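#' Specification of a parameter-identification run
#'
#' @param free_parameters Named list of length-2 numeric bounds for the
#'   constants to estimate, e.g.
#'   `list(cl_endo_spec = c(0.05, 10))` (1/min).  Names must match
#'   fields of [system_parameters()] or [drug_parameters()].
#' @param objective Only `"log_least_squares"` (sum of squared
#'   log-concentration residuals, the proportional-error convention of
#'   PK fitting).
#' @param n_starts Number of seeded multi-starts (hedges
#'   identifiability; all local minima are reported).
#' @param seed Integer seed for the start jitter.
#' @param reltol Optimizer convergence tolerance.
#' @param maxit Maximal iterations per start.
#' @return An object of class `fit_spec`.
#' @export
fit_spec <- function(free_parameters = list(cl_endo_spec = c(0.05, 10)),
                     objective = "log_least_squares",
                     n_starts = 5, seed = 1L, reltol = 1e-10,
                     maxit = 500) {
  objective <- match.arg(objective, "log_least_squares")
  if (length(free_parameters) == 0L)
    stop("at least one free parameter is required", call. = FALSE)
  for (nm in names(free_parameters)) {
    b <- free_parameters[[nm]]
    if (length(b) != 2L || any(!is.finite(b)) || any(b <= 0) || b[1] >= b[2])
      stop("bounds for '", nm, "' must be finite, positive and ordered",
           call. = FALSE)
  }
  structure(list(free_parameters = free_parameters, objective = objective,
                 n_starts = as.integer(n_starts), seed = as.integer(seed),
                 reltol = reltol, maxit = as.integer(maxit)),
            class = "fit_spec")
}

#' Fit model constants to concentration-time observations
#'
#' Minimises the sum of squared log-concentration residuals between the
#' observations and the simulated profile under `regimen`, over the
#' bounded free parameters of `spec`.  One-dimensional problems use
#' golden-section/parabolic search on the log scale; multi-dimensional
#' problems use seeded multi-start Nelder-Mead (all minima reported).
#' Simulation failures at a candidate are penalised, not fatal;
#' non-convergence is flagged on the result.
#'
#' @param model A [pbpk_model()] used as template (its individual, drug
#'   and system parameters are the fixed baseline).
#' @param observations A `concentration_profile` (e.g. from
#'   [read_profile_csv()] or [generate_synthetic_trial()]); only
#'   positive concentrations enter the objective.
#' @param regimen The [regimen()] under which the observations were
#'   collected.
#' @param spec A [fit_spec()].
#' @return An object of class `pbpk_fit` with `estimates`, residual
#'   standard error based `uncertainty`, `objective`, `converged`,
#'   `starts` (all multi-start minima) and `trace`.
#' @export
#' @examples
#' \donttest{
#' mod <- pbpk_model(virtual_individual(30, 70))
#' reg <- iv_standard(70, 5, 6); reg$events <- reg$events[1, , drop = FALSE]
#' obs <- simulate(mod, regimen = reg, end_time = 672,
#'                 t_grid = c(2, 24, 168, 336, 672))
#' fit_parameters(mod, obs, reg, fit_spec())$estimates
#' }
fit_parameters <- function(model, observations, regimen,
                           spec = fit_spec()) {
  stopifnot(inherits(model, "pbpk_model"), inherits(spec, "fit_spec"),
            inherits(regimen, "regimen"))
  keep <- observations$conc > 0
  obs_t <- observations$time[keep]
  obs_lc <- log(observations$conc[keep])
  if (length(obs_t) == 0L)
    stop("no positive observations to fit", call. = FALSE)
  end_time <- max(max(obs_t), max(regimen$events$time) + 1)
  pnames <- names(spec$free_parameters)
  lo <- vapply(spec$free_parameters, `[`, 0, 1)
  hi <- vapply(spec$free_parameters, `[`, 0, 2)

  template_ind <- model$individual
  template_ind$v_endosomal <- model$k$ve   # calibrated endosomal volume
  rebuild <- function(theta) {
    sys <- model$system; drg <- model$drug
    for (j in seq_along(pnames)) {
      nm <- pnames[j]
      if (nm %in% names(sys)) sys[[nm]] <- theta[j]
      else if (nm %in% names(drg)) drg[[nm]] <- theta[j]
      else stop("unknown parameter '", nm, "'", call. = FALSE)
    }
    pbpk_model(template_ind, drg, sys, calibration = NULL,
               tnf_mode = model$k$tnf_mode)
  }
  trace <- list()
  objective <- function(ltheta) {
    theta <- exp(ltheta)
    pen <- sum(pmax(0, log(lo / theta))^2 + pmax(0, log(theta / hi))^2)
    theta <- pmin(pmax(theta, lo), hi)
    val <- tryCatch({
      m <- rebuild(theta)
      prof <- simulate(m, regimen = regimen, end_time = end_time,
                       t_grid = sort(unique(c(obs_t, 0, end_time))))
      sim <- stats::approx(prof$time, prof$conc, xout = obs_t)$y
      if (any(!is.finite(sim)) || any(sim <= 0)) 1e10
      else sum((obs_lc - log(sim))^2)
    }, error = function(e) 1e10)
    val <- val + 1e4 * pen
    trace[[length(trace) + 1L]] <<- c(theta, objective = val)
    val
  }

  starts <- list()
  if (length(pnames) == 1L) {
    opt <- stats::optimize(objective, interval = log(c(lo, hi)),
                           tol = 1e-10)
    starts[[1]] <- list(par = opt$minimum, value = opt$objective,
                        convergence = 0L)
  } else {
    mid <- (log(lo) + log(hi)) / 2
    old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    set.seed(spec$seed)
    jit <- matrix(stats::runif(spec$n_starts * length(pnames), -0.5, 0.5),
                  nrow = spec$n_starts)
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
    jit[1, ] <- 0                      # first start at the midpoint
    for (s in seq_len(spec$n_starts)) {
      st <- mid + jit[s, ] * (log(hi) - log(lo)) / 2
      starts[[s]] <- stats::optim(st, objective, method = "Nelder-Mead",
                                  control = list(reltol = spec$reltol,
                                                 maxit = spec$maxit))
    }
  }
  values <- vapply(starts, function(s) s$value, 0)
  best <- starts[[which.min(values)]]
  est <- stats::setNames(pmin(pmax(exp(best$par), lo), hi), pnames)

  # residual-based uncertainty: from the curvature of the objective at
  # the optimum, objective = RSS on log-concentrations
  n <- length(obs_t); p <- length(pnames)
  sigma2 <- best$value / max(n - p, 1)
  unc <- rep(NA_real_, p)
  if (n > p) {
    h <- 1e-4
    for (j in seq_len(p)) {
      lt <- log(est)
      f0 <- best$value
      ltp <- lt; ltp[j] <- ltp[j] + h
      ltm <- lt; ltm[j] <- ltm[j] - h
      hess <- (objective(ltp) - 2 * f0 + objective(ltm)) / h^2
      if (is.finite(hess) && hess > 0)
        unc[j] <- sqrt(2 * sigma2 / hess) * est[j]  # delta method, log scale
    }
  }
  structure(list(
    estimates = est,
    uncertainty = stats::setNames(unc, pnames),
    objective = best$value,
    sigma = sqrt(sigma2),
    converged = is.null(best$convergence) || best$convergence == 0L,
    starts = data.frame(
      value = values,
      t(vapply(starts, function(s) exp(s$par), numeric(p)))
    ),
    n_obs = n,
    trace = do.call(rbind, trace)
  ), class = "pbpk_fit")
}

#' @export
print.pbpk_fit <- function(x, ...) {
  cat(sprintf("Parameter identification (%d observations, objective %.4g%s)\n",
              x$n_obs, x$objective,
              if (x$converged) "" else "; NOT converged"))
  for (nm in names(x$estimates))
    cat(sprintf("  %-16s %.5g (approx. SE %.3g)\n", nm, x$estimates[[nm]],
                x$uncertainty[[nm]]))
  invisible(x)
}

#' @export
coef.pbpk_fit <- function(object, ...) object$estimates

#' Write a fit result to JSON
#' @param x A `pbpk_fit`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fit_json <- function(x, path) {
  out <- list(estimates = as.list(x$estimates),
              uncertainty = as.list(x$uncertainty),
              objective = x$objective, sigma = x$sigma,
              converged = x$converged, n_obs = x$n_obs,
              starts = x$starts)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
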