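#' Build the reduced antibody disposition model for one individual
#'
#' Assembles the mechanistic model: a subcutaneous depot feeding plasma,
#' plasma exchanging with a lumped interstitial space, endosomal uptake
#' from both spaces, explicit mass-action binding of the drug to FcRn in
#' the endosome in competition with endogenous IgG, first-order
#' catabolism of unprotected endosomal antibody, recycling of FcRn-bound
#' antibody to plasma, and TNF-alpha target binding in plasma.
#'
#' The endosomal specific clearance defaults to 0.91 1/min for healthy
#' individuals and 1.6 1/min for IBD patients unless set explicitly in
#' `system`.  Two constants (total endosomal FcRn and the plasma to
#' interstitial exchange constant) are unpublished and must come either
#' from `system` or from a calibration object (see
#' [calibrate_reference_adult()]); by default the calibration shipped
#' with the package is used.
#'
#' @param individual A [virtual_individual()].
#' @param drug A [drug_parameters()].
#' @param system A [system_parameters()].
#' @param calibration A calibration object from [read_calibration()] /
#'   [calibrate_reference_adult()], or `NULL` to require both calibrated
#'   constants in `system`.
#' @param tnf_mode `"qe"` (quasi-equilibrium target binding, default),
#'   `"mass_action"` (explicit on/off kinetics) or `"off"`.
#' @param clamp_fcrn If `TRUE`, free FcRn is frozen at its drug-free
#'   equilibrium so the drug system becomes exactly linear (used for
#'   verification against closed-form linear ODE solutions).
#'
#' @return An object of class `pbpk_model`.
#' @export
#' @examples
#' adult <- virtual_individual(30, 70)
#' mod <- pbpk_model(adult)
#' coef(mod)["cl_sys_L_h"]  # analytic steady-state systemic clearance
pbpk_model <- function(individual,
                       drug = drug_parameters(),
                       system = system_parameters(),
                       calibration = read_calibration(),
                       tnf_mode = c("qe", "mass_action", "off"),
                       clamp_fcrn = FALSE) {
  stopifnot(inherits(individual, "virtual_individual"),
            inherits(drug, "drug_parameters"),
            inherits(system, "system_parameters"))
  tnf_mode <- match.arg(tnf_mode)
  if (is.na(system$fcrn_endo_conc) || is.na(system$k_dist)) {
    if (is.null(calibration))
      stop("calibration parameters 'fcrn_endo_conc' and 'k_dist' are unset ",
           "and no calibration was supplied", call. = FALSE)
    if (is.na(system$fcrn_endo_conc))
      system$fcrn_endo_conc <- calibration$fcrn_endo_conc
    if (is.na(system$k_dist)) system$k_dist <- calibration$k_dist
  }
  if (is.null(system$cl_endo_spec)) {
    system$cl_endo_spec <- if (individual$disease_state == "ibd") 1.6 else 0.91
  }

  vp <- individual$v_plasma
  vi <- individual$v_interstitial * system$int_access
  ve <- individual$v_endosomal
  # the endosomal reference volume is a calibrated constant: when a
  # calibration is in use and the individual was built with the default
  # reference volume, rescale the endosomal space accordingly
  if (!is.null(calibration) && !is.null(calibration$v_endo_ref) &&
      !is.null(individual$v_endo_ref))
    ve <- ve * calibration$v_endo_ref / individual$v_endo_ref

  # rate constants, internal units: hours, nmol, litres
  k <- list(
    vp = vp, vi = vi, ve = ve,
    mw = drug$molecular_weight,
    ka = drug$ka_sc,
    f_sc = drug$f_sc,
    k_pt = system$k_dist,
    k_tp = system$k_dist * vp / vi,
    up_p = system$f_uptake_plasma * system$k_uptake * 60 * ve / vp,
    up_i = (1 - system$f_uptake_plasma) * system$k_uptake * 60 * ve / vi,
    kon = drug$kass_fcrn * 60,                         # L/umol/h
    koff = drug$kass_fcrn * 60 * drug$kd_fcrn_endosome, # 1/h
    krec = system$k_recycle * 60,
    f_rec = system$f_recycle_plasma,
    clr = system$cl_endo_spec * 60,
    rtot = system$fcrn_endo_conc * ve * 1000,          # nmol
    kdeg_t = log(2) / system$tnf_halflife,
    tref = system$tnf_ref_conc / 1000 * vp,            # nmol
    kd_tnf = drug$kd_tnf / 1000,                       # nmol/L
    kon_tnf = drug$kon_tnf,                            # 1/h per nmol/L
    koff_tnf = drug$koff_tnf * 3.6e6,                  # 1/h
    complex_cleared = isTRUE(system$tnf_complex_cleared)
  )
  # endosomal free endogenous IgG, clamped at the healthy-reference
  # uptake/degradation balance (umol/L); see methods vignette
  g_endo <- system$igg_plasma_conc * system$k_uptake / 0.91
  kon_g <- system$kass_igg * 60
  koff_g <- kon_g * system$kd_igg_endosome
  # QSS IgG occupancy factor: GR = a (Rtot - EF - GR) => GR = a/(1+a) (Rtot-EF)
  k$a_igg <- kon_g * g_endo / (koff_g + k$krec)
  k$g_endo <- g_endo
  k$tnf_mode <- tnf_mode
  k$clamp_fcrn <- clamp_fcrn
  # drug-free equilibrium free FcRn concentration (umol/L)
  k$rf_eq <- (k$rtot / (1 + k$a_igg)) / ve / 1000

  structure(list(individual = individual, drug = drug, system = system,
                 k = k),
            class = "pbpk_model")
}

#' @export
print.pbpk_model <- function(x, ...) {
  cat("Reduced antibody PBPK model\n")
  print(x$individual)
  cat(sprintf("  endosomal clearance %.3g 1/min | FcRn total %.4g umol/L | k_dist %.4g 1/h\n",
              x$system$cl_endo_spec, x$system$fcrn_endo_conc, x$system$k_dist))
  cat(sprintf("  analytic systemic clearance %.4f L/h | TNF mode '%s'\n",
              coef(x)[["cl_sys_L_h"]], x$k$tnf_mode))
  invisible(x)
}

#' @export
coef.pbpk_model <- function(object, ...) {
  k <- object$k
  # steady-state fraction of endosomal input that is catabolised
  rf <- k$rf_eq
  fe <- k$clr / (k$clr + k$kon * rf * k$krec / (k$koff + k$krec))
  c(v_plasma_L = k$vp, v_interstitial_eff_L = k$vi, v_endosomal_L = k$ve,
    k_dist_per_h = k$k_pt, k_uptake_per_h = k$up_p * k$vp / k$ve /
      object$system$f_uptake_plasma,
    cl_endo_per_h = k$clr, fcrn_free_eq_umol_L = rf,
    fraction_catabolised = fe,
    cl_sys_L_h = fe * object$system$k_uptake * 60 * k$ve)
}

model_state_names <- c("depot", "plasma", "interstitial", "endosome_free",
                       "endosome_fcrn_bound", "tnf", "complex_tnf",
                       "eliminated")

#' Pre-dose steady state of the model
#'
#' Drug amounts are zero; FcRn/IgG occupancy and TNF-alpha turnover are
#' at their closed-form steady state.  With `verify = TRUE` the state is
#' additionally integrated for `verify_hours` with no input and the
#' maximal relative drift is checked.
#'
#' @param model A [pbpk_model()].
#' @param verify Integrate and check stationarity (default `FALSE`).
#' @param verify_hours Horizon of the verification integration.
#' @param tol Maximal allowed relative drift of any nonzero component.
#' @return Named state vector (nmol) with attributes `fcrn_free`,
#'   `igg_fcrn_bound` (nmol) and, if verified, `drift`.
#' @export
equilibrate <- function(model, verify = FALSE, verify_hours = 1000,
                        tol = 1e-3) {
  k <- model$k
  st <- stats::setNames(numeric(8), model_state_names)
  st["tnf"] <- k$tref
  gr <- k$a_igg / (1 + k$a_igg) * k$rtot
  attr(st, "igg_fcrn_bound") <- gr
  attr(st, "fcrn_free") <- k$rtot - gr
  if (verify) {
    out <- integrate_segment(model, st, times = c(0, verify_hours / 2,
                                                  verify_hours),
                             inf_rate = 0, rtol = 1e-10, atol = 1e-12)
    fin <- unname(out[nrow(out), -1])
    st0 <- unname(as.numeric(st))
    nz <- st0 != 0
    drift <- max(abs(fin[nz] - st0[nz]) / abs(st0[nz]))
    if (drift > tol)
      stop(sprintf(paste0("equilibrate: state drifted by %.3g relative ",
                          "over %g h (tolerance %g)"), drift, verify_hours,
                   tol), call. = FALSE)
    attr(st, "drift") <- drift
  }
  st
}

# quasi-equilibrium TNF complex (amount, nmol) given total drug and total
# TNF amounts in plasma
tnf_complex_qe <- function(p_tot, t_tot, vp, kd) {
  if (t_tot <= 0 || p_tot <= 0) return(0)
  d <- p_tot / vp; t <- t_tot / vp
  s <- d + t + kd
  c_conc <- 2 * d * t / (s + sqrt(s * s - 4 * d * t))
  c_conc * vp
}

# ODE right-hand side.  State meaning depends on tnf_mode:
#   qe / off : plasma = total drug in plasma (incl. target-bound), tnf =
#              total TNF, complex_tnf unused (0)
#   mass_action: plasma = free drug, tnf = free TNF, complex_tnf = complex
pbpk_rhs <- function(t, y, parms) {
  k <- parms$k
  inf_rate <- parms$inf_rate
  depot <- y[1]; p <- y[2]; i <- y[3]; e <- y[4]; ef <- y[5]
  tn <- y[6]; dt <- y[7]

  if (k$tnf_mode == "qe") {
    dt_amt <- tnf_complex_qe(p, tn, k$vp, k$kd_tnf)
    p_free <- p - dt_amt
  } else p_free <- p

  rf <- if (k$clamp_fcrn) k$rf_eq else
    ((k$rtot - ef) / (1 + k$a_igg)) / k$ve / 1000  # umol/L
  bind <- k$kon * rf * e
  unbind <- k$koff * ef

  upt_p <- k$up_p * p_free
  upt_i <- k$up_i * i
  rec <- k$krec * ef

  d_depot <- -k$ka * depot
  d_p <- inf_rate + k$ka * depot - k$k_pt * p_free + k$k_tp * i -
    upt_p + k$f_rec * rec
  d_i <- k$k_pt * p_free - k$k_tp * i - upt_i + (1 - k$f_rec) * rec
  d_e <- upt_p + upt_i - k$clr * e - bind + unbind
  d_ef <- bind - unbind - rec
  d_elim <- k$clr * e

  if (k$tnf_mode == "qe") {
    if (k$complex_cleared) {
      d_tn <- k$kdeg_t * (k$tref - tn)        # free and complex both cleared
      d_p <- d_p - k$kdeg_t * dt_amt
      d_elim <- d_elim + k$kdeg_t * dt_amt
    } else {
      d_tn <- k$kdeg_t * k$tref - k$kdeg_t * (tn - dt_amt)  # free TNF only
    }
    d_dt <- 0
  } else if (k$tnf_mode == "mass_action") {
    on <- k$kon_tnf * (tn / k$vp) * p_free
    off <- k$koff_tnf * dt
    d_tn <- k$kdeg_t * (k$tref - tn) - on + off
    k_c <- if (k$complex_cleared) k$kdeg_t else 0
    d_p <- d_p - on + off
    d_dt <- on - off - k_c * dt
    d_elim <- d_elim + k_c * dt
  } else {
    d_tn <- k$kdeg_t * (k$tref - tn)
    d_dt <- 0
  }
  list(c(d_depot, d_p, d_i, d_e, d_ef, d_tn, d_dt, d_elim))
}

#' Linearised drug rate matrix
#'
#' Rate matrix of the drug states (depot, plasma, interstitial, free
#' endosomal, FcRn-bound endosomal) with free FcRn frozen at its
#' drug-free equilibrium and target binding off.  Because the drug
#' occupies a negligible fraction of FcRn and of TNF-alpha at
#' therapeutic concentrations, this matrix describes the disposition
#' essentially exactly; it provides closed-form cross-checks
#' (matrix-exponential solutions, exact AUC and terminal eigenvalue).
#'
#' @param model A [pbpk_model()].
#' @return A 5 x 5 matrix, units 1/h.
#' @export
drug_rate_matrix <- function(model) {
  k <- model$k
  kon_rf <- k$kon * k$rf_eq
  A <- matrix(0, 5, 5,
              dimnames = list(model_state_names[1:5], model_state_names[1:5]))
  A["depot", "depot"] <- -k$ka
  A["plasma", "depot"] <- k$ka
  A["plasma", "plasma"] <- -(k$k_pt + k$up_p)
  A["plasma", "interstitial"] <- k$k_tp
  A["plasma", "endosome_fcrn_bound"] <- k$f_rec * k$krec
  A["interstitial", "plasma"] <- k$k_pt
  A["interstitial", "interstitial"] <- -(k$k_tp + k$up_i)
  A["interstitial", "endosome_fcrn_bound"] <- (1 - k$f_rec) * k$krec
  A["endosome_free", "plasma"] <- k$up_p
  A["endosome_free", "interstitial"] <- k$up_i
  A["endosome_free", "endosome_free"] <- -(k$clr + kon_rf)
  A["endosome_free", "endosome_fcrn_bound"] <- k$koff
  A["endosome_fcrn_bound", "endosome_free"] <- kon_rf
  A["endosome_fcrn_bound", "endosome_fcrn_bound"] <- -(k$koff + k$krec)
  A
}

# exact single-dose IV metrics from the linearised system: AUC_inf
# (mg*h/L), terminal eigenvalue (1/h) and systemic clearance (L/h)
linear_iv_metrics <- function(model, dose_mg) {
  A <- drug_rate_matrix(model)[-1, -1]   # no depot for IV dosing
  k <- model$k
  dose_nmol <- mg_to_nmol(dose_mg, k$mw)
  x_int <- solve(A, -c(dose_nmol, 0, 0, 0))   # integral of the state
  auc_nmolh_L <- unname(x_int[1]) / k$vp
  lam <- eigen(A, only.values = TRUE)$values
  lambda_z <- min(abs(Re(lam)))
  auc <- nmolL_to_mgL(auc_nmolh_L, k$mw)
  c(auc_inf = auc, lambda_z = lambda_z, cl = dose_mg / auc)
}

integrate_segment <- function(model, state, times, inf_rate, rtol, atol) {
  state <- stats::setNames(as.numeric(state), model_state_names)
  parms <- list(k = model$k, inf_rate = inf_rate)
  out <- deSolve::lsoda(y = state, times = times, func = pbpk_rhs,
                        parms = parms, rtol = rtol, atol = atol,
                        maxsteps = 100000)
  if (attr(out, "istate")[1] < 0)
    stop(sprintf("ODE solver failed near t = %.3f h", out[nrow(out), 1]),
         call. = FALSE)
  out
}
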