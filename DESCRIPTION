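Package: hiphopr
Title: Comparative Chemogenomic Fitness Profiling for Pooled Yeast
    Deletion Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for scoring, comparing and clustering large-scale
    chemogenomic (HIPHOP) fitness screens of pooled barcoded yeast
    deletion collections. Implements both published scoring conventions
    (robust z-score fitness defects from tag intensities, and
    replicate-adjusted MADL with gene-wise standardization), clearance
    based drug-target (HIP hit) calling, coinhibition and cofitness
    Pearson similarity with significance zeroing, Ward clustering with
    dynamic branch cutting to discover chemogenomic response signatures,
    hypergeometric gene-set enrichment, and overlap-coefficient matching
    of signatures across independent datasets. Ships a synthetic-data
    generator that plants response classes, gene signatures and
    single-gene drug targets so the full pipeline can be validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    limma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
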