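Package: nurepress
Title: Phased Nucleosome Arrays and Transcriptional Repressor Inference in
    Repressive Chromatin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@nurepress.org",
           role = c("aut", "cre"))
Description: Detects well-phased nucleosome arrays inside repressive
    chromatin domains from DANPOS-style nucleosome calls, stratifies the
    arrays into accessibility-defined subtypes from ATAC-seq Tn5 insertion
    profiles using Gaussian-mixture clustering with silhouette-based model
    selection, builds cross-sample state-transition matrices over union
    regions, and combines subtype-level repressive efficacy with
    distance-resolved motif enrichment and expression change to rank
    candidate transcriptional repressors. Ships a deterministic synthetic
    landscape generator so the whole pipeline is testable at toy scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
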