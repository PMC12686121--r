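Package: zgakit
Title: Calling and Interpretable Modelling of Zygotic Genome Activation Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies zygotic genome activation (ZGA) genes from staged
    preimplantation expression tables using species-specific TPM-ratio rules,
    builds k-mer spectrum features from strand-aware TSS/TES flanks and binned
    histone-mark signal features around the TSS, trains and tunes
    SVM/random-forest/logistic/gradient-boosting classifiers with
    MIC-ranked incremental feature selection, interprets them with exact
    tree Shapley attributions (including pairwise interactions), links salient
    k-mers to transcription-factor motifs via a Tomtom-style PWM comparator
    with MEME minimal format import/export, and screens genomes for
    high-confidence ZGA genes. Ships a coupled synthetic-data generator with
    planted sequence and chromatin structure so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    ranger,
    e1071,
    glmnet,
    xgboost,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
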