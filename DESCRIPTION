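Package: climaxent
Title: Maximum-Entropy Climatic Suitability Modelling with Bioclimatic
    Indices, MESS Novelty Mapping and Habitat Envelopes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Presence-background species distribution modelling on gridded
    climate data. Derives thirteen bioclimatic variables (annual summaries,
    Kira warmth/coldness indices, Holdridge biotemperature and potential
    evapotranspiration ratio, humidity index) from monthly temperature and
    precipitation grids; fits an L1-regularized maximum-entropy (Gibbs)
    model over linear, quadratic, product, threshold and hinge features;
    evaluates it by presence-background ROC/AUC with k-fold cross-validation
    and AUC-weighted ensemble prediction; maps multivariate environmental
    similarity (MESS) and per-cell limiting factors; classifies suitability
    into habitat classes and extracts per-class climatic envelopes. Includes
    a synthetic-landscape generator with known ground truth so the whole
    pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
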