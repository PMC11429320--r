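#' Construct a virtual individual
#'
#' Builds the biometric description of one simulated subject and derives
#' the three drug-accessible compartment volumes of the reduced body
#' structure (plasma, lumped interstitial space, lumped endosomal space).
#' Volumes scale with body weight through configurable per-kg fractions
#' and scaling exponents (default exponent 1, i.e. strictly linear).
#'
#' @param age Age in years, in `[0, 120]`.
#' @param body_weight Body weight in kg, in `[3, 250]`.
#' @param disease_state `"healthy"` or `"ibd"`; selects the endosomal
#'   clearance default downstream.
#' @param id Identifier string.
#' @param plasma_fraction Plasma volume per kg, L/kg.
#' @param interstitial_fraction Anatomical interstitial volume per kg, L/kg.
#' @param v_endo_ref Endosomal reference volume of a 70 kg adult, L.  The
#'   accessible endosomal volume is `f_endo * v_endo_ref * (weight/70)^exp`.
#' @param f_endo Accessible fraction of the endosomal reference volume.
#' @param exponents Named numeric vector of weight-scaling exponents for
#'   `plasma`, `interstitial` and `endosomal` volumes (defaults all 1).
#'
#' @return An object of class `virtual_individual` with fields `id`,
#'   `age`, `body_weight`, `v_plasma`, `v_interstitial`, `v_endosomal`
#'   (litres) and `disease_state`.
#' @export
#' @examples
#' virtual_individual(30, 70)                     # typical adult
#' virtual_individual(14, 60, "ibd")              # older child with IBD
virtual_individual <- function(age, body_weight,
                               disease_state = c("healthy", "ibd"),
                               id = NULL,
                               plasma_fraction = 0.0414,
                               interstitial_fraction = 0.16,
                               v_endo_ref = 0.5,
                               f_endo = 0.20,
                               exponents = c(plasma = 1, interstitial = 1,
                                             endosomal = 1)) {
  disease_state <- match.arg(disease_state)
  if (!is.numeric(age) || length(age) != 1L || is.na(age) ||
      age < 0 || age > 120)
    stop("'age' must be a single value in [0, 120] years", call. = FALSE)
  if (!is.numeric(body_weight) || length(body_weight) != 1L ||
      is.na(body_weight) || body_weight < 3 || body_weight > 250)
    stop("'body_weight' must be a single value in [3, 250] kg", call. = FALSE)
  ex <- c(plasma = 1, interstitial = 1, endosomal = 1)
  ex[names(exponents)] <- exponents
  w <- body_weight
  rel <- w / 70
  out <- list(
    id = if (is.null(id)) sprintf("ind_%gkg_%gy", w, age) else as.character(id),
    age = age,
    body_weight = w,
    v_plasma = plasma_fraction * 70 * rel^ex[["plasma"]],
    v_interstitial = interstitial_fraction * 70 * rel^ex[["interstitial"]],
    v_endosomal = f_endo * v_endo_ref * rel^ex[["endosomal"]],
    disease_state = disease_state,
    v_endo_ref = v_endo_ref,
    exponents = ex
  )
  stopifnot(out$v_plasma > 0, out$v_interstitial > 0, out$v_endosomal > 0)
  structure(out, class = "virtual_individual")
}

#' @export
print.virtual_individual <- function(x, ...) {
  cat(sprintf("Virtual individual '%s': %g y, %g kg, %s\n",
              x$id, x$age, x$body_weight, x$disease_state))
  cat(sprintf("  V plasma %.3f L | V interstitial %.2f L | V endosomal %.4f L\n",
              x$v_plasma, x$v_interstitial, x$v_endosomal))
  invisible(x)
}

#' @export
as.data.frame.virtual_individual <- function(x, ...) {
  data.frame(id = x$id, age_y = x$age, weight_kg = x$body_weight,
             v_plasma_L = x$v_plasma, v_interstitial_L = x$v_interstitial,
             v_endosomal_L = x$v_endosomal, disease_state = x$disease_state,
             stringsAsFactors = FALSE)
}

#' Specification of a virtual pediatric population stratum
#'
#' One weight band of the stratified pediatric population.  Ages are
#' sampled uniformly over the ages whose weight-by-age anchor (a
#' piecewise-linear curve through 20 kg at 6 years and 70 kg at
#' 18 years) can reach the band within +/- 3 coefficients of variation;
#' individual weights are lognormal around the anchor, truncated to the
#' band.
#'
#' @param n_per_band Number of individuals in the band.
#' @param age_range Length-2 numeric, years (min, max).
#' @param weight_band Length-2 numeric, kg (min, max).
#' @param weight_cv Lognormal coefficient of variation of weight around
#'   the age anchor.
#' @param seed Integer seed; sampling is fully reproducible.
#' @param disease_state Disease state given to every sampled individual.
#'
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_per_band = 50,
                            age_range = c(6, 18),
                            weight_band,
                            weight_cv = 0.15,
                            seed = 1L,
                            disease_state = "ibd") {
  stopifnot(length(age_range) == 2L, length(weight_band) == 2L,
            age_range[1] < age_range[2], weight_band[1] < weight_band[2],
            n_per_band >= 1, weight_cv >= 0)
  structure(list(n_per_band = as.integer(n_per_band),
                 age_range = as.numeric(age_range),
                 weight_band = as.numeric(weight_band),
                 weight_cv = weight_cv, seed = as.integer(seed),
                 disease_state = disease_state),
            class = "population_spec")
}

# anchor weight (kg) for a given age (years): linear through (6, 20), (18, 70)
weight_anchor <- function(age) 20 + (age - 6) * (50 / 12)
anchor_age <- function(weight) 6 + (weight - 20) * (12 / 50)

#' Sample a virtual population
#'
#' Draws `n_per_band` virtual individuals for one weight band, with hard
#' truncation of weights to the band and of ages to the age range.
#' Deterministic under the spec's seed; the caller's RNG state is left
#' untouched.
#'
#' @param spec A [population_spec()].
#' @param ... Passed on to [virtual_individual()] (e.g. volume fractions).
#'
#' @return A list of `virtual_individual` objects with attribute `spec`.
#' @export
#' @examples
#' pop <- sample_population(population_spec(10, weight_band = c(45, 70)))
#' range(vapply(pop, function(p) p$body_weight, numeric(1)))
sample_population <- function(spec, ...) {
  stopifnot(inherits(spec, "population_spec"))
  cv <- spec$weight_cv
  sdlog <- sqrt(log(1 + cv^2))
  wb <- spec$weight_band
  # ages whose anchor weight can reach the band within 3 (log) CVs
  spread <- exp(3 * sdlog)
  a_lo <- max(spec$age_range[1], anchor_age(wb[1] / spread))
  a_hi <- min(spec$age_range[2], anchor_age(wb[2] * spread))
  if (!is.finite(a_lo) || !is.finite(a_hi) || a_lo >= a_hi)
    stop("weight band [", wb[1], ", ", wb[2], "] kg is unreachable from the ",
         "age range at CV ", cv, call. = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)
  n <- spec$n_per_band
  out <- vector("list", n)
  for (i in seq_len(n)) {
    age <- stats::runif(1, a_lo, a_hi)
    mu <- log(weight_anchor(age)) - sdlog^2 / 2  # mean of LN = anchor
    # exact truncated-lognormal draw by inverse CDF
    p_lo <- stats::plnorm(wb[1], mu, sdlog)
    p_hi <- stats::plnorm(wb[2], mu, sdlog)
    if (p_hi - p_lo <= 0)
      stop("could not draw a weight inside the band for age ", round(age, 1),
           call. = FALSE)
    w <- stats::qlnorm(p_lo + stats::runif(1) * (p_hi - p_lo), mu, sdlog)
    w <- min(max(w, wb[1] + 1e-9), wb[2] - 1e-9)
    out[[i]] <- virtual_individual(age, w, spec$disease_state,
                                   id = sprintf("sub%03d", i), ...)
  }
  attr(out, "spec") <- spec
  class(out) <- "virtual_population"
  out
}

#' @export
print.virtual_population <- function(x, ...) {
  sp <- attr(x, "spec")
  w <- vapply(x, function(p) p$body_weight, numeric(1))
  cat(sprintf("Virtual population: n = %d, band %g-%g kg, ages %g-%g y (seed %d)\n",
              length(x), sp$weight_band[1], sp$weight_band[2],
              sp$age_range[1], sp$age_range[2], sp$seed))
  cat(sprintf("  weight median %.1f kg (range %.1f-%.1f)\n",
              stats::median(w), min(w), max(w)))
  invisible(x)
}

#' @export
as.data.frame.virtual_population <- function(x, ...) {
  do.call(rbind, lapply(x, as.data.frame))
}

#' Write a population to CSV
#'
#' Columns: `id, age_y, weight_kg, v_plasma_L, v_interstitial_L,
#' v_endosomal_L, disease_state`.
#'
#' @param population A `virtual_population` or list of individuals.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_population_csv <- function(population, path) {
  df <- if (is.data.frame(population)) population else
    do.call(rbind, lapply(population, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
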