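Package: natkit
Title: Discovery and Expression Analysis of Natural Antisense Transcripts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A strand-aware toolkit for discovering natural antisense
    transcripts (NATs) overlapping a user-supplied list of genes in a GTF
    transcript annotation. Classifies sense-antisense overlap as exonic,
    intronic and/or promoter-associated, groups antisense transcripts into
    loci, proposes strand-safe qPCR assay regions, aggregates fragment-level
    FPKM into locus expression across subcellular compartments, and provides
    the qPCR statistical layer (delta-Ct relative expression, one-way ANOVA
    with Tukey HSD, two-sample t tests, Pearson sense-antisense concordance).
    Ships seeded generators for synthetic annotations, fragment tables and Ct
    tables with machine-readable truth, so every step is testable offline.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
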