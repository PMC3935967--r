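Package: meftop
Title: Topology-Focused Quality Assessment and Re-Ranking of Protein Structure Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-model quality assessment for template-based protein
    structure prediction, aimed at low-homology ("dawn region") targets where
    threading Z-scores are unreliable. Extracts 37 sequence-versus-model
    agreement features in four groups (secondary-structure and accessibility
    composition, residue contact-map agreement, secondary-structure-element
    contact features, and 3D topology descriptors), trains a weighted epsilon-SVR
    to predict model TM-score (P-score), and combines it with a threading
    Z-score into an M-score used to re-rank candidate models. Includes a
    deterministic synthetic-fold generator so the full extract-train-score
    -evaluate pipeline runs without external data, plus TM-score computation
    and the standard Top1%/average-rank evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Rcpp,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
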