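---
title: "Methods: a reduced PBPK model of infliximab disposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a reduced PBPK model of infliximab disposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Why a reduced structure

Whole-body PBPK platforms describe antibody disposition with organ-level
two-pore extravasation, organ-specific endosomal spaces and lymph
return. Every *printed* parameter that identifies infliximab kinetics,
however, lives at the endosome: uptake (0.29 min⁻¹), recycling
(0.30 min⁻¹), FcRn affinities at acidic and neutral pH, endogenous-IgG
competition, and the specific endosomal clearance that carries the
disease signal (0.91 min⁻¹ healthy, 1.6 min⁻¹ in IBD). Organ geometry
is not identifiable from plasma concentration data — only the product
of endosomal volume and rate constants is. `ifxpbpk` therefore lumps
the body into four drug-accessible spaces: an SC depot, plasma, one
interstitial pool and one endosomal pool, keeping all endosome-level
processes explicit:

* **Plasma ⇄ interstitial** exchange at `k_dist` (h⁻¹, referenced to
  plasma), with the back-rate chosen so concentrations equalise at
  steady state over the *antibody-accessible* interstitial volume.
* **Endosomal uptake** at `k_uptake · V_endo`, split 0.53/0.47 between
  plasma and interstitial space.
* **FcRn salvage**: explicit mass action (`kon = Kass`,
  `koff = Kass · Kd`), in competition with endogenous IgG; bound drug
  is recycled to plasma (`f_recycle_plasma = 1`), free endosomal drug
  is degraded at `cl_endo_spec`. Neutral-pH binding (Kd 4.54 mmol/L
  drug, 10 mmol/L IgG) is treated as absent, which is what those
  affinities mean numerically.
* **Target binding**: a single plasma TNF-α pool with zero-order
  synthesis and first-order turnover, held at its 0.20 pmol/L
  reference concentration before dosing.

States are amounts in nmol; time is in hours; per-minute and per-ms
constants are converted at model build. Concentrations are reported in
mg/L via the molecular weight (149.9 kDa; 1 mg/L = 6.671 nmol/L).

## Key physiological choices

**Interstitial accessibility.** The anatomical interstitial space
(0.16 L/kg) is not freely available to a 150 kDa antibody: steric
exclusion by the extracellular matrix limits IgG to roughly a fifth of
it. The model multiplies the anatomical volume by a fixed accessible
fraction `int_access = 0.2`. Without it the steady-state volume of
distribution would be ~0.2 L/kg and the terminal half-life close to a
month — incompatible with the 0.07 L/kg and ~10 days that characterise
infliximab.

**Endogenous IgG.** Free endosomal IgG is clamped at the
healthy-reference uptake/degradation balance
(`igg_plasma_conc · k_uptake / 0.91 min⁻¹` ≈ 22 µmol/L at 70 µmol/L
plasma IgG). IgG homeostasis is actively regulated; letting the
endosomal IgG pool collapse when disease raises `cl_endo_spec` would
free FcRn and silently cancel most of the disease effect on drug
clearance. IgG–FcRn occupancy is treated as quasi-steady-state
(it relaxes within minutes); drug–FcRn binding stays a full ODE.

**TNF-α complexes.** With a 0.2 pmol/L target and a 120 pmol/L Kd the
complexed drug fraction is always tiny, but what happens to the complex
matters at low concentrations: clearing it at the (fast) TNF turnover
rate would add a linear target-mediated clearance of
`kdeg · V · T_ref / Kd ≈ 0.003 L/h`, visibly steepening the washout
below ~0.2 mg/L and contradicting the observed half-life/trough
pattern. The default (`tnf_complex_cleared = FALSE`) therefore protects
the complex — only free TNF turns over, complexes accumulate (as
antibody–cytokine complexes do clinically), and target binding is
pharmacokinetically inert, which the dose-linearity tests assert.
Binding defaults to quasi-equilibrium; the literal off-rate
(1.33 ms⁻¹) makes explicit kinetics needlessly stiff, and a
mass-action mode with a slowed off-rate verifies the equivalence.

## Calibration of the three unprinted constants

Three constants are required that no published table provides: the
total endosomal FcRn concentration `fcrn_endo_conc`, the exchange
constant `k_dist`, and the endosomal reference volume `v_endo_ref`.
`calibrate_reference_adult()` tunes them once so the healthy 70 kg
adult, after a single 350 mg 2-h infusion, reproduces the reference
simulated metrics AUC∞ = 40,311 mg·h/L, Cmax = 110 mg/L and
Vz = 0.07 L/kg. The optimizer works on a smooth surrogate — the drug
system is linear at tracer-level receptor occupancy, so AUC∞ comes from
a rate-matrix solve and the terminal slope from its smallest
eigenvalue, with only the 2-h infusion simulated for Cmax — and the
result is re-verified with the full nonlinear simulation plus NCA
(residuals ≤ 0.1%). The calibrated values
(`fcrn_endo_conc ≈ 602 µmol/L`, `k_dist ≈ 0.102 h⁻¹`,
`v_endo_ref ≈ 0.0217 L`) ship in `inst/extdata/calibration.json`
together with the achieved metrics.

Two remarks. First, the calibrated FcRn concentration is an *effective*
lumped constant: because only `kon·[FcRn]·V_endo` is identifiable, it
absorbs whatever endosomal geometry the reduced structure discards.
Second, a large endosomal reference volume is untenable here: recycling
returns interstitially captured drug to plasma, so a fast endosomal
turnover drains the interstitial pool (its concentration falls to ~20%
of plasma) and collapses the apparent volume of distribution; the
calibration settles on a small reference volume that restores
near-equilibration. After this single calibration, every scenario —
IBD adult, SC switch, heavy adult, pediatric, population — runs with no
further tuning; only the published disease switch of `cl_endo_spec`
and the individual's biometrics change.

## Scaling, individuals and populations

Compartment volumes scale linearly with body weight (per-kg fractions:
plasma 0.0414 L/kg, interstitial 0.16 L/kg; endosomal volume
proportional to weight/70). Scaling exponents are configurable per
volume but default to 1, including for children: an ontogeny model is
deliberately out of scope, and we chose not to bend the pediatric
exponent to reproduce published pediatric simulations, because the
exponent that would do so (~1.7 on the endosomal space) is
physiologically backwards (clearance growing superlinearly with
weight) and wrecks the weight-band dose search (a 25 kg child would
inherit a 20-day half-life). The known consequence: with 5 mg/kg
dosing and strictly linear scaling, a child's concentration profile is
mathematically identical to the adult's, so pediatric IV troughs are
lower than ontogeny-aware whole-body simulations report (~1.6 vs
~2.1 mg/L at week 30). This limitation is visible as a deliberately
failing acceptance check rather than papered over.

Populations are sampled per weight band: age uniform over the ages
whose weight-by-age anchor (piecewise linear through 20 kg at 6 y and
70 kg at 18 y) can reach the band within 3 lognormal CVs; weight drawn
from a lognormal around the anchor (CV 0.15) truncated to the band by
inverse-CDF sampling (exact, rejection-free, reproducible under the
spec seed; the caller's RNG state is restored afterwards).

## Regimens, simulation and NCA conventions

Dose events are exact multiples of 168 h, so 54-week schedules carry no
floating drift. The solver (lsoda, rtol 1e-8, atol 1e-10 nmol) is hard
restarted at every dose event and infusion end; IV doses are zero-order
infusions, SC doses enter the depot already corrected for
bioavailability (0.79 × nominal). Mass balance
(depot + body + eliminated vs administered bioavailable dose) is
checked at every reported time and stays below 1e-6 relative in all
scenarios; halving the tolerances moves reported metrics by < 0.01%.

NCA uses the linear-up/log-down trapezoid; AUC∞ adds `C_last/λz`.
The terminal slope is a log-linear regression over an automatically
selected window: all windows ending at the last washout sample with at
least 3 points are scored by adjusted R², the best one wins, and
windows below R² = 0.999 are disqualified (an estimation error if none
qualifies — e.g. a profile truncated before its terminal phase). On
noise-free simulated washouts this converges to the terminal
eigenvalue of the disposition matrix. Troughs are pre-dose samples:
the reporting grid always contains every dose time minus 1e-6 h;
requesting a week without a dose event returns the interpolated
concentration flagged `non_trough`. The apparent volume of
distribution is reported as `Vz = CL/λz` (primary, matching the
"apparent volume" convention for antibody NCA) with `Vss` from moment
analysis also available.

## The dose search

`suggest_dose()` simulates every candidate flat SC dose over the band
population (IV induction weeks 0/2, switch at week 6, q2w), reads the
pre-dose trough at the latest dose at or beyond week 22 (week 30 at the
default horizon), and selects the smallest candidate whose trough
distribution is *comparable* to the adult post-switch reference range
(11–20 mg/L). Comparability is deliberately a coverage criterion: the
median **and** the 5th percentile must reach the window's lower bound,
so no part of the population is underexposed; troughs above the window
are tolerated, since moderately higher pediatric troughs have not been
flagged as a safety concern. A median-only rule (`rule = "median"`) is
available; it is laxer at the heavy end of the band spectrum (80 mg
already puts the 45–70 kg median inside the window while leaving its
5th percentile below 11 mg/L). The SC interval (2 weeks) follows the
approved flat-fixed maintenance layout and is configurable, as are the
candidate grid and the target window.

## The synthetic trial generator

`generate_synthetic_trial()` produces the observation sets the
identification machinery is exercised against, replacing digitized
trial figures which are not shipped: (i) a healthy-adult single-dose IV
profile from a two-compartment reference whose micro-constants are
solved numerically so its NCA metrics equal the printed trial values
(AUC 38,000 mg·h/L — hence CL 0.0092 ≈ 0.01 L/h, Cmax 121 mg/L,
Vz 0.09 L/kg; the central volume must be solved too, since 350 mg in
2.9 L of plasma cannot reach 121 mg/L); (ii) an IBD multidose IV trough
series (CL 0.015 L/h, terminal half-life 9.5 d); (iii) a post-switch SC
trough series (adds a first-order depot, solved by
eigen-decomposition). Noise is multiplicative lognormal with CV 0.15 by
default — a typical bioanalytical plus residual variability, declared
here because the true residual noise of digitized data is unknowable.
The generator emulates average (typical-patient) profiles only: no
between-subject variability structure beyond the lognormal noise, no
ADA-driven clearance drift, no dropout. Recovery tests on these data
therefore show estimator correctness under the assumed error model,
not robustness to real-world trial messiness.

## Parameter identification

`fit_parameters()` minimises the sum of squared log-concentration
residuals (the proportional-error convention of PK fitting; alternative
weighting is a matter of swapping the objective) over bounded
parameters: golden-section/parabolic search on the log scale for one
parameter, seeded multi-start Nelder-Mead (5 starts, all minima
reported) otherwise. Simulation failures at a candidate are penalised,
not fatal; non-convergence flags the result. On self-generated
noise-free data the healthy endosomal clearance is recovered to < 1%;
at 15% proportional noise with 12 samples the estimator shows < 2%
bias and ~5% RMSE over seeds, and the healthy/IBD clearance ratio is
recovered to ~1.76 (= 1.6/0.91) when both datasets are fitted.

## Problem sizes and numerical notes

The shipped tests and acceptance checks run at desk scale by choice:
single-individual scenarios over 30–60 weeks (2,500–7,000 reporting
points), the full population dose search at 3 bands × 50 subjects × 4
candidate doses (600 ODE solves, ~3 min on one CPU), and 12-seed
Monte-Carlo for recovery. Degenerate inputs are first-class: zero
endosomal clearance gives a closed, mass-conserving system; zero IgG
frees all FcRn; a zero-CV generator is exactly the reference curve;
dose-free weeks are flagged rather than silently interpolated.

## Known limitations

* No organ-level two-pore distribution, lymph flow or tissue
  concentrations; plasma PK only.
* No ontogeny of FcRn or endosomal capacity — pediatric scaling is
  strictly linear (see above), and the heavy (120 kg) adult scales
  linearly too, which likely overstates clearance at high weight.
* Anti-drug-antibody kinetics are not modelled; their effect is only
  present insofar as it is lumped into the IBD endosomal clearance.
* The calibrated FcRn/endosomal constants are effective parameters of
  the reduced geometry, not measurements.
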