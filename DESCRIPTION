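Package: lncproject
Title: LncRNA-Disease Association Prediction by Integrated-Similarity Space Projection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores candidate lncRNA-disease associations on a bipartite
    network by projecting integrated similarity vectors onto
    similarity-weighted association profiles. Implements DAG-based disease
    semantic similarity, best-match-average lncRNA functional similarity,
    Gaussian interaction profile kernel similarity, their integration,
    weighted-network reconstruction and vector space projection scoring,
    together with leave-one-out evaluation protocols for known
    associations, new lncRNAs and isolated diseases, a parameter-sweep
    harness, and a planted-block synthetic data generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
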