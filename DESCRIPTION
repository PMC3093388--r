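Package: plasmaquant
Title: Isotope-Pair Quantitative Plasma Proteomics and Confounder-Aware
    Differential Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential analysis of isotopically labeled (heavy/light
    acrylamide) plasma proteomics experiments. Reads per-event heavy/light
    intensity tables, computes event and protein case/control log2 ratios,
    tests protein-level shifts with a one-sample t-test and with an
    empirical null built from a split-sample control-control labeling
    experiment, and calls proteins differential at a fold-change and
    p-value threshold. Cross-model tools compare differential plasma
    profiles between disease models (Venn regions, overlap percentages,
    Pearson correlation, abundance-pattern classes) and prioritize
    proteins altered in cancer models but in none of the confounding
    (inflammation or angiogenesis) models. A synthetic-data generator
    emulates the protein/peptide/event hierarchy with known ground truth
    so every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
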