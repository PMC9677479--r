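Package: kgensemble
Title: Ensemble Link Prediction over Knowledge Graph Embedding Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for combining the drug-disease predictions of several
    knowledge graph embedding models into ensemble rankings. Provides triple
    file input/output with a drug/protein/disease schema, drug-disease-focused
    train/validation/test splitting, lightweight embedding scorers (TransE,
    DistMult, ComplEx, RotatE) with negative-sampling training, percentile
    thresholding of per-model score tables with min-max, sigmoid and rank
    normalization onto a common scale, sum/average/product-of-experts/position
    score aggregation, Precision-at-K evaluation with pairwise top-K agreement
    analysis and degree-score correlation, and a synthetic generator for
    knowledge graphs and multi-model score tables with planted positives and
    controllable cross-model agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
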