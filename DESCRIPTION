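Package: kbcistrome
Title: Predicting NF-kB (p65) Recruitment from the Pre-Stimulation Chromatin Landscape
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to model stimulus-induced NF-kB (p65) recruitment from
    chromatin features measured before stimulation. The package builds
    regulatory sites by merging transcription-factor ChIP-seq peaks, classifies
    them by accessibility, TSS proximity, occupancy stage, CpG-island and
    DNA-methylation context, scales histone-mark signals into [0,1],
    decomposes mark patterns into non-negative "chromatin codes" (NMF),
    fits MCC-tuned regularized logistic models of p65 binding, quantifies
    per-TF and pairwise cooperativity enrichment, mines combinatorial
    TF-clusters by greedy Fisher-test optimization and top-k non-redundant
    association rules, links regulatory sites to genes, and ships a synthetic
    data generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    glmnet,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
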