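Package: symbiopart
Title: Host-Symbiont Transcript Partitioning and Caste-Biased Expression
    Analysis for Lower-Termite Metatranscriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing mixed host-symbiont (termite-flagellate)
    bulk transcriptomes sequenced from worker and soldier castes. Partitions
    assembled transcripts into host, flagellate and unclear sources from
    BLAST-style similarity hit tables using a best-hit plus
    conflict-region rule with top-five consensus assignment of flagellate
    order and genus; filters and TMM-normalizes count matrices; tests
    caste-biased differential abundance with a negative-binomial Wald
    test and Benjamini-Hochberg correction; selects caste biomarker
    transcripts by L1-penalized logistic regression; builds per-caste
    weighted co-expression networks with topological overlap and a
    consensus network, and extracts flagellate-host strong pairs;
    performs hypergeometric functional-term enrichment. Includes a
    synthetic-data generator with planted ground truth so the whole
    pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    glmnet
Config/testthat/edition: 3
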