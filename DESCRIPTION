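Package: phenoscreen
Title: Fluorescence Image-Based Phenomic Profiling of Cell-Line Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for intensity-based phenomic profiling of
    cell-line panels screened with fluorescent probe libraries: a synthetic
    plate-screen generator (factorial designs over probes, lines,
    concentrations, channels, sites, time points and replicates, with
    origin-specific turn-on effects, batch effects and multiplicative noise),
    Otsu-threshold foreground quantification of pooled well images, kinetic
    fold-change (48 h / 1 h) feature matrices with probe selectivity indices,
    hierarchical clustering with an origin-purity diagnostic, and from-scratch
    stepwise linear discriminant analysis (Wilks' lambda, partial-F
    enter/remove at alpha 0.150, per-class classification score functions,
    jackknifed cross-validation matrices and top-two-score plots), modelled on
    the NCI-60 panel of 60 cancer cell lines from 9 tissues of origin.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tidyselect,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    ape,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
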