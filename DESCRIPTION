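Package: dualflow
Title: Dual-Input Tracer Kinetic Modeling for DCE-MRI of Thoracic Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Continuous-time tracer kinetic modeling of dynamic
    contrast-enhanced MRI for tumors with a dual (pulmonary plus systemic
    arterial) blood supply.  Implements five kinetic models (Tofts-Kety,
    extended Tofts-Kety, two-compartment exchange, adiabatic approximation
    to the tissue homogeneity, and distributed parameter) under pulmonary,
    systemic, or dual arterial input; a two-pass parametric arterial input
    function with recirculation; variable flip angle T1 mapping and spoiled
    gradient-echo signal-to-concentration conversion; seeded multistart
    bound-constrained voxelwise fitting; corrected-AIC model selection with
    Akaike weights; a seeded digital perfusion phantom; and summary
    statistics (bootstrap medians, Wilcoxon and Pearson comparisons, kernel
    density of the pulmonary flow fraction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    RNifti,
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
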