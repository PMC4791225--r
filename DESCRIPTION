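Package: itrtools
Title: Inferred Transcriptional Regulator Analysis for Multi-Omic Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the activity of transcriptional regulators (genes,
    proteins or chemical compounds) from differential-expression and
    gene-set evidence matched against a signed regulator-to-target prior
    network: hypergeometric target-overlap enrichment plus a signed
    activation z-score per regulator. Integrates regulator rankings across
    conditions (top-N overlap matrices, common cores, induced
    protein-interaction subnetworks with pathway enrichment), derives
    directional gene signatures from the contributing targets and
    stratifies patient survival cohorts, normalizes 384-well RNAi
    viability screens (loess surface correction on the sample fraction of
    the plate, robust z-scores, log2 fold-change hit calls), classifies
    ChIP peaks by genomic context, and generates fully synthetic
    planted-truth datasets so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
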