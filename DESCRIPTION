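Package: tugwar
Title: Tug-of-War Moran Models of Tumor Evolution and Site Frequency Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-driven simulation of two constant-population Moran-type
    "tug-of-war" models of tumor evolution, in which rare advantageous driver
    mutations compete with frequent slightly deleterious passengers. Model A
    draws both the dying and the replacing cell proportionally to fitness and
    preserves expected fitness under drift; Model B draws the dying cell
    uniformly and is biased toward fitness increase. The package tracks full
    clone genealogies, computes observed site frequency spectra (SFS) and their
    cumulative tails, evaluates theoretical expected spectra (Griffiths-Tavare
    coalescent form, Durrett exponential-growth approximations, a multiclone
    binomial-hump model, and power-law comparison curves), runs Ewens
    sampling formula neutrality tests (allele-count Kolmogorov-Smirnov and
    singleton Wilcoxon procedures), and corrects coverage-depth bias between
    paired tumor variant tables by total-count histogram equalization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
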