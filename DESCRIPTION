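Package: factoseq
Title: Factorial RNA-Seq Analysis from Quality Control to Co-Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of multifactorial bulk RNA-seq count data:
    input validation for complete factorial designs, low-count filtering and
    TMM/RLE normalization with quality-control summaries, automatic
    generation of named contrasts (averaged, per-modality and interaction)
    over a negative-binomial generalized linear model, per-gene
    likelihood-ratio testing with Cox-Reid dispersion estimation, Venn/set
    operations over gene lists, Gaussian-mixture co-expression clustering
    with a two-loop small-EM strategy and ICL model selection, and
    hypergeometric enrichment of annotation terms. A seeded synthetic-data
    generator plants differential expression, co-expression clusters and
    enriched terms so the whole workflow is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    edgeR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    DESeq2,
    optparse
Config/testthat/edition: 3
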