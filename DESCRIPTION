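Package: phosdyn
Title: Insulin-Responsive Phosphoproteome Dynamics and Kinase-Substrate Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for SILAC phosphoproteomics screens of insulin
    signalling: regulation calling from log2 ratios by median-absolute-deviation
    thresholding, classification of PI3K/mTOR- and Akt-inhibitor dependence by a
    reversal-fraction rule, temporal feature extraction (min-max scaling, area
    under the curve, quadratic fits) and fuzzy c-means clustering of nine-point
    insulin time courses, phosphorylation-motif statistics (position-specific
    scoring matrices and percent-difference enrichment), and an SVM-ensemble
    kinase-substrate predictor with delta scores and Pareto ranking. Includes a
    synthetic-data generator that emulates the inhibitor and time-course screens
    with planted ground truth, so every stage can be benchmarked without access
    to raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    jsonlite,
    e1071,
    Biostrings,
    pracma,
    generics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
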