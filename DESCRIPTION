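Package: girkrates
Title: Agonist Binding Kinetics from GIRK Current Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates association (k_on) and dissociation (k_off) rate
    constants of G-protein-coupled receptor agonists from the activation and
    deactivation kinetics of G-protein-coupled inwardly rectifying potassium
    (GIRK) channel currents, as recorded by two-electrode voltage clamp in
    Xenopus oocytes. Provides an ODE simulator of the receptor to G-protein to
    GIRK cascade (including finite solution-exchange kinetics and recording
    noise) for generating synthetic voltage-clamp traces, monoexponential and
    sigmoidal concentration-response fitting, linear-range k_obs analysis,
    kinetic K_d computation with uncertainty propagation, exact-permutation
    Spearman correlation, and summary-statistics two-way ANOVA with Sidak
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
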