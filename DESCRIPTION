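Package: mregnet
Title: Differential Expression, Enrichment and Master-Regulator Network
    Analysis for T-Cell RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A transparent re-implementation of a bulk RNA-seq downstream
    workflow for antigen-specific CD4+/CD8+ T cells contrasted between a
    myocarditis-resistant and a susceptible mouse strain: FPKM
    quantification with an expressed-gene filter and PCA ordination,
    negative-binomial Wald differential expression with
    Benjamini-Hochberg adjustment, hypergeometric over-representation
    analysis, ranked-list gene set enrichment (running-sum ES with
    permutation NES and FDR q-values), integration of transcription
    factor-target priors from multiple sources into DEG-centered
    regulatory subnetworks with connectivity-ranked master regulators,
    and 2^-ddCt qPCR relative quantification. A seeded synthetic-data
    generator plants known differential expression, coherently shifted
    gene sets and master transcription factors so that every stage is
    verifiable by recovery of ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    tools,
    rlang,
    ggplot2,
    patchwork,
    igraph,
    jsonlite,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr
Config/testthat/edition: 3
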