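Package: spongescout
Title: Discovery of lncRNA-Mediated ceRNA (miRNA Sponge) Triplets from
    Matched Expression Profiles
Version: 0.1.0
Authors@R:
    person("Gozde", "Aydin", email = "gozde.aydin@example.org",
           role = c("aut", "cre"))
Description: An integrative pipeline for discovering lncRNA:miRNA:mRNA
    competing-endogenous-RNA ("sponge") triplets from matched expression
    matrices: Spearman partial-correlation screening with a sensitivity
    score, kernel-based unconditional and conditional independence tests
    with simulated eigenvalue nulls, and filtering by miRNA-target
    database support.  Downstream analyses identify triplets whose joint
    expression pattern stratifies patient survival (log-rank tests with
    an f-score summary), cluster co-expressed mRNAs sharing a
    lncRNA:miRNA pair (Ward clustering with Mojena's stopping rule), and
    annotate genomically proximal triplets.  A synthetic-data module
    generates expression, survival, target-database and annotation
    inputs with planted sponge structure and known ground truth so the
    whole pipeline can be exercised and calibrated without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    GenomicRanges,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
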