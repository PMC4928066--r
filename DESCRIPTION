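Package: taxadecay
Title: Distance-Decay, Matrix Regression and Functional-Gene Profiling for
    Soil Microbial Biogeography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for testing biogeographic endemism and functional
    redundancy in soil microbial communities sampled along environmental
    gradients. Implements power-law distance-decay estimation of the
    community turnover exponent z with bootstrap significance tests,
    single and multiple regression on distance matrices (MRM) with
    Mantel-style permutation inference, principal component analysis,
    correspondence analysis and detrending-by-segments detrended
    correspondence analysis (DCA), alpha diversity and rarefaction of OTU
    count tables, and the three-step detection/normalisation/category-sum
    pipeline for functional gene array (GeoChip) signal intensities.
    Ships a synthetic-data generator that emulates a multi-site
    latitudinal sampling design so every stage of the pipeline can be
    tested against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    biomformat,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
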