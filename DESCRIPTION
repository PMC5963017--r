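Package: revsig
Title: Disease-Signature Reversal Analysis for RNA-Seq Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-usable pipeline for connectivity-map-style drug
    reversal analysis of bulk RNA-seq experiments: low-count filtering,
    trimmed-mean-of-M-values (TMM) normalization, precision-weighted
    gene-wise linear models with empirical-Bayes moderated t-statistics and
    Benjamini-Hochberg FDR control, assembly of disease signatures (single
    study or two-study Stouffer meta-analysis), cosine-similarity reversal
    scoring with a gene-permutation null, directional preranked gene-set
    enrichment, hypergeometric over-representation, and a simplified
    negative-binomial test for differential exon/junction usage.  A
    negative-binomial count simulator with planted disease and
    dose-dependent reversal effects provides ground truth for every stage.
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
    MASS,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    edgeR,
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
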