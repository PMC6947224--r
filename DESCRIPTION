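Package: sexcallr
Title: Sex Inference for RNA-Seq Samples from Y-Chromosome Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the genetic sex of bulk RNA-seq samples from the
    expression of Y-chromosome-linked genes. Reads gene-level count data
    (HTSeq-count files or a genes-by-samples matrix), normalizes to counts
    per million (CPM), selects Y-linked marker genes whose per-sample CPM is
    bimodal (high in males, near-zero mismapping artifacts in females),
    scores each sample by the summed CPM over those genes, and classifies
    samples as male or female by thresholds on that score. A leading
    log-fold-change multidimensional-scaling embedding verifies that samples
    segregate into two sex groups, and a negative-binomial count simulator
    generates sexed datasets with known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    tools,
    utils
Suggests:
    edgeR,
    jsonlite,
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
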