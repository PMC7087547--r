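Package: idcenet
Title: Differential Co-Expression Networks for Comparing Diseased and
    Aging Brain Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A comparative functional-genomics workflow for contrasting
    brain gene-expression cohorts, built around differential
    co-expression. Provides quality screening of test/control microarray
    cohorts (PCA separation scoring and DEG-based two-way hierarchical
    clustering, with greedy sample pruning), differential expression with
    moderated or ordinary t-statistics and Benjamini-Hochberg FDR,
    selection of differentially co-expressed gene pairs by a Fisher-z
    heterogeneity Q statistic with gain/loss-of-co-expression labelling,
    construction of protein-protein-interaction-integrated gene networks
    (IGN) and their once-removed extensions (xIGN) with iterative degree
    filtering, Fisher's exact gene-set over-representation with
    type-1/type-2 disruption calls, and a cross-case signature layer
    (disease-only hit selection, pathway augmentation, overlap summaries,
    case clustering). A synthetic-data generator with known planted
    ground truth makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    limma,
    jsonlite,
    yaml,
    ape,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
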