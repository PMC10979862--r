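Package: hypertx
Title: Quantifying RNAPII Hypertranscription from Paired Tumor/Normal
    Fragment Data
Version: 0.1.0
Authors@R:
    person("hypertx", "maintainers", email = "maintainers@hypertx.dev",
           role = c("aut", "cre"))
Description: Downstream analysis of antibody-tethered tagmentation (CUTAC)
    fragment data for detecting genome-wide RNAPII hypertranscription in
    tumors relative to matched normal tissue. Builds genome-scaled
    normalized coverage tracks from mapped-fragment BED files, computes
    per-regulatory-element tumor minus normal statistics (Bland-Altman and
    MA values, rank-ordered difference curves, cross-tumor composites),
    histone-gene-cluster and mitochondrial-fraction proxies, paired-control
    sparse-enrichment peak calls, megabase-scale amplicon tiling with local
    regression summit detection, and TF-IDF/PCA/UMAP sample embeddings.
    Ships a synthetic paired tumor/normal fragment simulator with a planted
    ground-truth ledger so the full pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    Matrix,
    stats,
    utils,
    tools,
    methods
Suggests:
    uwot,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
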