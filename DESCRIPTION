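Package: satseq
Title: Sequencing-Depth Saturation Analysis for 3' mRNA-Seq Molecular
    Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding how deeply to sequence 3' mRNA-Seq
    libraries used as molecular phenotypes. Implements seeded
    without-replacement (hypergeometric) downsampling of gene-by-sample
    count matrices, expressed- and informative-gene detection rules,
    a two-group negative-binomial Wald differential-expression stage,
    precision/recall/F-score benchmarking of subsampled gene and variant
    sets against full-depth truth sets, asymptotic saturation-curve
    fitting with an analytic plateau (saturation depth) estimate, and
    post-calling variant hard filters with strand-aware 3' gene-body
    positional-bias summaries. Includes synthetic-data generators for
    counts, saturation observations, gene models and variant records so
    the full pipeline can be exercised and validated without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
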