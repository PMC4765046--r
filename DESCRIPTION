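Package: netlmm
Title: Network-Guided Linear Mixed Models for Trans-eQTL Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Trans-eQTL association mapping with network-guided covariate
    selection. For every SNP-gene test the method discovers V-structures
    (colliders) in the local gene regulatory network, anchored by genes with
    an established cis or trans association to the tested variant, and
    conditions on the identified exogenous genes through a low-rank linear
    mixed model with a realized-relationship background covariance. Includes
    an eQTL simulation framework (basic regulatory motifs, sparse and
    star-shaped gene networks with confounding), reference comparator
    methods (PC-LMM, PCselect-LMM, ICE-LMM, oracle conditioning), and
    power/calibration evaluation via partial AUC at low false-positive rates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
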