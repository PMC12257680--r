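Package: woolres
Title: Resilience Indicators from Longitudinal Wool Fibre Diameter and Body Weight
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying resilience in sheep from longitudinal wool
    fibre-diameter profiles and body-weight records. Raw records are converted
    to penalized B-spline curves, phase variation is removed by square-root
    velocity function (SRVF) elastic alignment to flock-year Frechet means,
    and seven resilience indicators are derived from the deviations
    (log-variance, lag-1 autocorrelation, skewness, mean absolute change, and
    weaning response/recovery rates plus area between curves). Heritabilities
    and genetic/phenotypic correlations of the indicators are estimated with
    single-step genomic animal models (pedigree A, VanRaden G, blended H) by
    restricted maximum likelihood. Includes a synthetic pedigree and
    longitudinal-phenotype simulator emulating the data structure the analysis
    assumes, and an end-to-end pipeline with reproducible CSV interfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    graphics,
    grDevices,
    jsonlite,
    splines,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
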