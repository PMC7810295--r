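Package: rfacurve
Title: Parameterization of Radiofrequency Ablation Impedance Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Landmark parameterization of the circuit-impedance curve recorded
    during radiofrequency ablation (RFA). Extracts seven curve parameters
    (procedure duration to first roll-off, its midpoint, the time and value of
    minimum impedance, and the initial, midpoint and roll-off impedances) from
    equipment logs, derives three performance indices (the asymmetry index
    delta, the Drop Ratio and the Ascent Ratio), and runs the cohort-level
    statistical battery used in ex vivo ablation studies: normality and
    homogeneity checks, one- and two-way ANOVA with Tukey HSD, BCa bootstrap
    confidence intervals, Spearman index-volume correlations, Tukey-fence
    outlier flagging and estimated marginal means. Includes a synthetic cohort
    generator that emulates a five-group ex vivo bovine study so the full
    pipeline runs without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    emmeans,
    jsonlite,
    purrr,
    readr,
    readxl,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    boot,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
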