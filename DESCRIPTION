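Package: corexpr
Title: Cross-Species RNA-Seq Comparison via Common Orthologous Regions
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the CORE (Common Orthologous REgions) approach to
    direct cross-species comparison of RNA-Seq time courses: reciprocal
    best-hit ortholog identification from BLAST tabular hits, HSP-derived
    paired BED interval sets, alignment filtering to orthologous regions,
    gene-level counting, and a combined two-species differential-expression
    engine (CPM filtering, TMM normalization, precision-weighted moderated
    t-statistics, species-by-time interaction contrasts). Also provides
    Spearman co-expression network construction with dynamic scale-free /
    small-world threshold selection, discrete power-law maximum-likelihood
    fitting with bootstrapped goodness of fit, regulator-centered subnetwork
    extraction, assembly quality metrics (N50 / ExN50), and deterministic
    synthetic-data generators for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    igraph,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    limma
Config/testthat/edition: 3
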