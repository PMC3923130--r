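Package: mirage
Title: MicroRNA Evolutionary Age, Sequence Divergence, and Developmental
    Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to relate microRNA evolutionary age and sequence
    divergence to developmental expression profiles. Implements parsimony
    dating of microRNA family origins on a ranked species tree,
    reciprocal-best-hit ortholog pairing with optional synteny support,
    region-partitioned divergence estimation (substitutions per site and
    Kimura two-parameter distances over hairpin, mature, seed, and
    loop/stem-extension regions), small RNA-seq read filtering, counting
    and RPM normalization, stage-wise conservation-expression statistics
    (divergence-tertile composition, per-stage rank correlations), and
    transcriptome age/divergence indices (TAI/TDI) with bootstrap
    standard deviations. Includes a phylogeny-aware synthetic-data
    generator with recorded ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    ggplot2,
    jsonlite,
    Rcpp,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
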