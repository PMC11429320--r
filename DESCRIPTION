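Package: ifxpbpk
Title: Reduced Physiologically Based Pharmacokinetic Simulation of
    Infliximab in Inflammatory Bowel Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mechanistic disposition model for the anti-TNF-alpha
    monoclonal antibody infliximab, reduced to the drug-accessible spaces
    that govern IgG pharmacokinetics: a subcutaneous depot, plasma, a
    lumped interstitial space, and a lumped endosomal space with explicit
    FcRn binding, competition with endogenous IgG, catabolic clearance of
    unprotected antibody, and recycling to plasma.  Includes virtual
    individuals and stratified virtual pediatric populations, intravenous
    induction/maintenance and subcutaneous switch regimens, stiff ODE
    simulation with dose events, non-compartmental exposure metrics
    (AUC, Cmax, troughs, terminal half-life, clearance), parameter
    identification from concentration-time data, a synthetic trial-data
    generator, and a trough-matched weight-band dose search for pediatric
    subcutaneous dosing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
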