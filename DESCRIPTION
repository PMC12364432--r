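Package: carayaclim
Title: Ensemble Niche Modeling, Dispersal-Constrained Projection and
    Landscape Metrics for the Black-and-Gold Howler Monkey
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for projecting present and future climatically
    suitable areas of Alouatta caraya: occurrence cleaning (range buffer,
    one-per-cell thinning), collinearity screening of bioclimatic predictors
    (VIF and pairwise Pearson filters), ensemble suitability modeling (Bioclim
    envelope and ridge logistic regression under a pluggable scorer contract,
    bootstrap 70/30 evaluation with AUC and TSS, max(se+sp) thresholding),
    GCM-then-SSP scenario consensus with a 2-of-3 vote, dispersal-constrained
    range projection from a home-range allometry, woody-fragment
    fragmentation and connectivity indices, maintained/lost/gained area
    accounting, climate refuges, and protected-area overlap. A synthetic-data
    module generates every input with known ground truth so the full workflow
    is exercisable without downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    grDevices,
    igraph,
    jsonlite,
    mgcv,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
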