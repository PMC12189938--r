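Package: fiescan
Title: Detecting Fisheries-Induced Evolution from Otoliths and Temporal Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking phenotypic change in exploited fish stocks to
    genomic signatures of selection using time-series samples. Implements
    chemical aging of otoliths from element-ratio profiles, hierarchical
    Bayesian von Bertalanffy growth modelling with back-calculation of body
    length, temporal autocovariance of allele-frequency change with block
    bootstrap and permutation nulls, windowed Weir-Cockerham Fst, nucleotide
    diversity and divergence scans, inversion genotyping by local PCA,
    kinship-based mixed-model association scans of growth performance, and a
    randomization test for the overlap of association outliers with
    differentiation outlier windows. Ships forward simulators (Wright-Fisher
    drift and polygenic size-selective mortality) that generate all pipeline
    inputs with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
LinkingTo: Rcpp
RoxygenNote: 7.3.3
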