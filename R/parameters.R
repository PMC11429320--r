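#' Drug-specific parameters for the antibody disposition model
#'
#' Physicochemical and binding constants of infliximab together with the
#' first-order subcutaneous absorption constants.  Defaults are the
#' published infliximab values; any subset can be overridden.
#'
#' @param molecular_weight Molecular weight, kDa.
#' @param solute_radius Hydrodynamic (solute) radius, nm.  Recorded for
#'   provenance; the reduced model does not use it directly.
#' @param kd_fcrn_endosome Dissociation constant for FcRn at endosomal pH,
#'   µmol/L.
#' @param kd_fcrn_neutral Dissociation constant for FcRn at neutral pH,
#'   mmol/L.  At the default (4.54 mmol/L) binding in plasma/interstitial
#'   space is negligible and is treated as absent.
#' @param kass_fcrn Association rate constant for FcRn, L/µmol/min.
#' @param kd_tnf Dissociation constant for TNF-alpha, pmol/L.
#' @param koff_tnf Dissociation rate constant for TNF-alpha, 1/ms.
#' @param f_sc Subcutaneous bioavailability (fraction of the nominal dose
#'   reaching the depot).
#' @param ka_sc First-order subcutaneous absorption rate constant, 1/h.
#'
#' @return An object of class `drug_parameters` (a named list).  The
#'   TNF-alpha association constant `kon_tnf` (1/h per nmol/L) is derived
#'   once as `koff_tnf / kd_tnf` and cached.
#' @export
#' @examples
#' drug_parameters()
#' drug_parameters(ka_sc = 0.02)
drug_parameters <- function(molecular_weight = 149.9,
                            solute_radius = 5.18,
                            kd_fcrn_endosome = 0.73,
                            kd_fcrn_neutral = 4.54,
                            kass_fcrn = 0.72,
                            kd_tnf = 120.17,
                            koff_tnf = 1.33,
                            f_sc = 0.79,
                            ka_sc = 0.0114) {
  p <- list(
    molecular_weight = molecular_weight,
    solute_radius = solute_radius,
    kd_fcrn_endosome = kd_fcrn_endosome,
    kd_fcrn_neutral = kd_fcrn_neutral,
    kass_fcrn = kass_fcrn,
    kd_tnf = kd_tnf,
    koff_tnf = koff_tnf,
    f_sc = f_sc,
    ka_sc = ka_sc
  )
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0) {
      stop("drug parameter '", nm, "' must be a single positive number",
           call. = FALSE)
    }
  }
  if (f_sc > 1) stop("drug parameter 'f_sc' must not exceed 1", call. = FALSE)
  # kon = koff / Kd, converted to 1/h per (nmol/L):
  # koff [1/ms] -> 1/h: * 1000 * 3600 ; kd [pmol/L] -> nmol/L: / 1000
  p$kon_tnf <- (koff_tnf * 3.6e6) / (kd_tnf / 1000)
  structure(p, class = "drug_parameters")
}

#' System (physiological) parameters for the antibody disposition model
#'
#' Endosomal sorting constants, FcRn and endogenous-IgG pools, TNF-alpha
#' turnover and the plasma/interstitial exchange constant.  Defaults are
#' the published healthy-adult values; the endosomal specific clearance
#' switches to the disease value when a model is built for an IBD
#' individual (see [pbpk_model()]).
#'
#' Two constants are not published and are obtained by the one-time
#' calibration ([calibrate_reference_adult()]): the total endosomal FcRn
#' concentration `fcrn_endo_conc` and the plasma-interstitial exchange
#' constant `k_dist`.  They default to `NA` here and are filled in from
#' the stored calibration when a model is built.
#'
#' @param f_endo Drug-accessible fraction of the endosomal reference
#'   volume (dimensionless).
#' @param cl_endo_spec Specific clearance of unprotected antibody in the
#'   endosomal space, 1/min.  `NULL` (default) selects 0.91 for healthy
#'   and 1.6 for IBD individuals at model build time.
#' @param f_recycle_plasma Fraction of FcRn-recycled antibody returned to
#'   plasma (remainder to interstitial space).
#' @param f_uptake_plasma Fraction of endosomal uptake drawn from plasma
#'   (remainder from the interstitial space).
#' @param k_uptake Rate constant for endosomal uptake, 1/min (referenced
#'   to the endosomal volume).
#' @param k_recycle Rate constant for recycling of FcRn-bound antibody
#'   from the endosomal space, 1/min.
#' @param fcrn_endo_conc Total FcRn concentration in the endosomal space,
#'   µmol/L.  Calibration parameter.
#' @param igg_plasma_conc Endogenous IgG plasma concentration, µmol/L
#'   (70 µmol/L is about 10.5 g/L).
#' @param kd_igg_neutral Endogenous IgG-FcRn dissociation constant at
#'   neutral pH, µmol/L (10,000 means no binding in plasma).
#' @param kd_igg_endosome Endogenous IgG-FcRn dissociation constant in
#'   the endosome, µmol/L.
#' @param kass_igg Endogenous IgG-FcRn association rate constant,
#'   L/µmol/min.
#' @param tnf_ref_conc TNF-alpha reference (pre-dose steady-state) plasma
#'   concentration, pmol/L.
#' @param tnf_halflife TNF-alpha plasma turnover half-life, h.
#' @param tnf_complex_cleared If `TRUE`, the drug-TNF complex is
#'   eliminated at the TNF degradation rate; if `FALSE` (default) the
#'   complex is protected and only free TNF turns over, so target
#'   binding is pharmacokinetically inert.
#' @param k_dist Plasma-to-interstitial distribution rate constant, 1/h
#'   (referenced to plasma).  Calibration parameter.
#' @param int_access Antibody-accessible fraction of the anatomical
#'   interstitial volume (steric exclusion of IgG by the extracellular
#'   matrix).
#'
#' @return An object of class `system_parameters` (a named list).
#' @export
#' @examples
#' system_parameters()
#' system_parameters(cl_endo_spec = 1.6)  # IBD endosomal clearance
system_parameters <- function(f_endo = 0.20,
                              cl_endo_spec = NULL,
                              f_recycle_plasma = 1,
                              f_uptake_plasma = 0.53,
                              k_uptake = 0.29,
                              k_recycle = 0.30,
                              fcrn_endo_conc = NA_real_,
                              igg_plasma_conc = 70,
                              kd_igg_neutral = 10000,
                              kd_igg_endosome = 0.63,
                              kass_igg = 0.87,
                              tnf_ref_conc = 0.20,
                              tnf_halflife = 1,
                              tnf_complex_cleared = FALSE,
                              k_dist = NA_real_,
                              int_access = 0.2) {
  p <- list(
    f_endo = f_endo,
    cl_endo_spec = cl_endo_spec,
    f_recycle_plasma = f_recycle_plasma,
    f_uptake_plasma = f_uptake_plasma,
    k_uptake = k_uptake,
    k_recycle = k_recycle,
    fcrn_endo_conc = fcrn_endo_conc,
    igg_plasma_conc = igg_plasma_conc,
    kd_igg_neutral = kd_igg_neutral,
    kd_igg_endosome = kd_igg_endosome,
    kass_igg = kass_igg,
    tnf_ref_conc = tnf_ref_conc,
    tnf_halflife = tnf_halflife,
    tnf_complex_cleared = isTRUE(tnf_complex_cleared),
    k_dist = k_dist,
    int_access = int_access
  )
  chk_pos <- function(nm, allow_na = FALSE, allow_zero = FALSE) {
    x <- p[[nm]]
    if (is.null(x)) return(invisible())
    ok <- is.numeric(x) && length(x) == 1L &&
      ((allow_na && is.na(x)) || (is.finite(x) && (x > 0 || (allow_zero && x == 0))))
    if (!ok) stop("system parameter '", nm, "' is invalid", call. = FALSE)
  }
  chk_pos("f_endo"); chk_pos("cl_endo_spec", allow_zero = TRUE)
  chk_pos("k_uptake")
  chk_pos("k_recycle"); chk_pos("fcrn_endo_conc", allow_na = TRUE)
  chk_pos("igg_plasma_conc", allow_zero = TRUE)
  chk_pos("kd_igg_neutral"); chk_pos("kd_igg_endosome"); chk_pos("kass_igg")
  chk_pos("tnf_ref_conc", allow_zero = TRUE); chk_pos("tnf_halflife")
  chk_pos("k_dist", allow_na = TRUE); chk_pos("int_access")
  for (nm in c("f_recycle_plasma", "f_uptake_plasma")) {
    x <- p[[nm]]
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
      stop("system parameter '", nm, "' must lie in [0, 1]", call. = FALSE)
  }
  if (p$f_endo > 1 || p$int_access > 1)
    stop("fractions 'f_endo' and 'int_access' must lie in (0, 1]", call. = FALSE)
  structure(p, class = "system_parameters")
}

#' @export
print.drug_parameters <- function(x, ...) {
  cat("Antibody drug parameters\n")
  cat(sprintf("  molecular weight : %.1f kDa\n", x$molecular_weight))
  cat(sprintf("  Kd FcRn (endosome / neutral): %.2f umol/L / %.2f mmol/L\n",
              x$kd_fcrn_endosome, x$kd_fcrn_neutral))
  cat(sprintf("  Kass FcRn        : %.2f L/umol/min\n", x$kass_fcrn))
  cat(sprintf("  Kd TNF-alpha     : %.2f pmol/L (koff %.2f 1/ms)\n",
              x$kd_tnf, x$koff_tnf))
  cat(sprintf("  SC absorption    : F = %.2f, ka = %.4f 1/h\n",
              x$f_sc, x$ka_sc))
  invisible(x)
}

#' @export
print.system_parameters <- function(x, ...) {
  cat("System (physiology) parameters\n")
  cl <- if (is.null(x$cl_endo_spec)) "by disease state (0.91 / 1.6)" else
    sprintf("%.3g", x$cl_endo_spec)
  cat(sprintf("  endosomal clearance: %s 1/min; uptake %.2f 1/min; recycle %.2f 1/min\n",
              cl, x$k_uptake, x$k_recycle))
  cat(sprintf("  uptake split plasma/interstitial: %.2f / %.2f; recycled to plasma: %.2f\n",
              x$f_uptake_plasma, 1 - x$f_uptake_plasma, x$f_recycle_plasma))
  cat(sprintf("  FcRn total (endosome): %s umol/L [calibrated]\n",
              format(x$fcrn_endo_conc)))
  cat(sprintf("  k_dist: %s 1/h [calibrated]; interstitial access %.2f\n",
              format(x$k_dist), x$int_access))
  cat(sprintf("  TNF-alpha ref %.2f pmol/L, half-life %.1f h\n",
              x$tnf_ref_conc, x$tnf_halflife))
  invisible(x)
}

# mg/L plasma -> nmol/L given molecular weight in kDa (1 kDa = 1000 g/mol)
mgL_to_nmolL <- function(conc_mg_per_L, molecular_weight_kDa) {
  conc_mg_per_L * 1e6 / (molecular_weight_kDa * 1000)
}

nmolL_to_mgL <- function(conc_nmol_per_L, molecular_weight_kDa) {
  conc_nmol_per_L * (molecular_weight_kDa * 1000) / 1e6
}

mg_to_nmol <- function(amount_mg, molecular_weight_kDa) {
  amount_mg * 1e6 / (molecular_weight_kDa * 1000)
}

nmol_to_mg <- function(amount_nmol, molecular_weight_kDa) {
  amount_nmol * (molecular_weight_kDa * 1000) / 1e6
}
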