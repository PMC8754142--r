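Package: qnq
Title: Population Dynamics of Quiescent and Nonquiescent Yeast Under
    Starvation and Regrowth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses the ecology of quiescent (Q) and
    nonquiescent (NQ) subpopulations of starving budding yeast. Provides an
    ordinary differential equation model of growth, differentiation,
    starvation with nutrient recycling, and lagged regrowth on fresh medium;
    protocol-level scenario composition (weekly regrowth assays after long
    starvation in simple or complex environments, freezing pre-stress, and a
    short-starvation experiment); plate-reader growth-curve analytics
    (OD600-to-biomass conversion, two lag-phase estimators, relative-biomass
    normalisations); group comparisons (one-way ANOVA with Tukey HSD and
    Welch t tests); a synthetic plate-reader data generator with replicate
    structure and measurement noise; and parameter calibration by a
    differential-evolution global optimiser.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
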