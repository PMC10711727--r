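Package: grasprsa
Title: Representational Similarity Analysis of Grasp Planning and Execution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for representational similarity
    analysis (RSA) of condition-wise multivoxel activity patterns from a
    factorial visuomotor grasping design. Encodes a nine-condition design
    (grasp axis x grasp size x object mass) with mutually uncorrelated binary
    model dissimilarity matrices, simulates subject-level voxel beta patterns
    and grasp-comfort ratings with known planted representational structure,
    computes correlation-distance representational dissimilarity matrices
    (RDMs), relates neural RDMs to model RDMs with noise ceilings, one-tailed
    Wilcoxon signed-rank group inference and Benjamini-Hochberg false
    discovery rate control, maps second-order inter-region similarity within
    and across task phases with Bonferroni thresholding, hierarchical
    clustering and classical multidimensional scaling, and analyses
    grasp-comfort ratings against model and neural geometries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
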