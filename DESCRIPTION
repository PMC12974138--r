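Package: gutstab
Title: Longitudinal Gut Microbiota Stability Analysis for Two-Arm Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for analysing gut-microbiota
    stability in two-arm longitudinal studies: alpha/beta diversity with
    PERMANOVA, SparCC compositional correlation networks with permutation
    pseudo-p-values, natural-connectivity robustness curves, maximal-clique
    centrality (MCC) keystone ranking, linear mixed-model and LEfSe
    differential-genus screens with intersection logic, and Spearman
    association matrices against reproductive outcomes. Ships a
    ground-truth-aware synthetic compositional data generator so every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    vegan,
    igraph,
    lme4,
    lmerTest,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
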