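Package: oxylink
Title: Hemoglobin-Oxygen Equilibria, Heterotropic Linkage and Blood-Gas
    Physiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing hemoglobin-oxygen equilibration
    experiments in the tradition of comparative blood-gas physiology:
    Hill-plot estimation of half-saturation pressure (P50) and
    cooperativity (n50) restricted to the 30-70% saturation window,
    heterotropic linkage coefficients (Bohr and CO2 Bohr factors,
    chloride sensitivity, 2,3-DPG effect), integrated van't Hoff
    oxygenation enthalpies with correction for the heat of oxygen
    solubilization, empirical temperature coefficients, pH-corrected
    whole-blood affinities, and derived red-cell indices with Welch
    group comparisons. Includes a forward allosteric simulator of
    equilibration data under effector and temperature conditions so
    every estimator is verifiable by parameter recovery, and a
    sequence-level audit of beta-type globin chains for substitutions
    and conservation of the canonical DPG-binding residues.
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
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
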