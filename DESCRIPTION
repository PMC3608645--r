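Package: ragscore
Title: Consensus Reliability Scoring of Endometrial Receptivity Gene Signatures
Version: 0.1.0
Authors@R:
    person("HGEx", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Cross-study vote-counting meta-analysis of curated endometrial
    gene lists. Ingests per-dataset gene calls (expressed / not-detected /
    up / down), harmonizes gene symbols through a user-supplied alias map,
    computes per-gene reliability scores (two points per supporting dataset,
    kept separately for opposing calls) for expression status and expression
    pattern between two conditions, combines them into cumulative scores, and
    classifies consistently behaving genes into Up-Ex (expressed and
    upregulated in the receptive phase) and Down-Nd (not-detected and
    downregulated) receptivity-associated gene sets. Includes a synthetic
    corpus generator with known ground truth for parameter-recovery
    validation, packaged transcriptions of the published 179-gene result for
    regression testing, and small quantification utilities for qPCR relative
    expression (2^-ddCt) and spheroid attachment percentages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
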