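Package: interfish
Title: Interphase FISH Amplification Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of interphase fluorescence in situ hybridization (FISH)
    images for focal oncogene amplification. Provides deterministic FISH foci
    detection by projection onto an orthogonalized Gaussian kernel
    (stat-FISH), min-cut splitting of touching nuclei, histogram- and
    kurtosis-based image quality gates, per-nucleus classification of the
    amplification mechanism (extrachromosomal DNA versus homogeneously
    staining region versus no amplification) with bootstrap sample-level
    aggregation, and a maximum-likelihood estimator of fluorescent-tagging
    accuracy in mixed-population experiments. Includes a seeded synthetic
    image generator with planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    tiff,
    png,
    utils
Suggests:
    optparse,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
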