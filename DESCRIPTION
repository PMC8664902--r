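Package: medipdmr
Title: Window-Based Differential DNA Methylation Analysis for MeDIP-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An epigenome-wide association workflow for MeDIP-Seq style
    enrichment data: tiles a genome into fixed 1 kb windows, counts sonicated
    fragments per window by their midpoints, tests each window for
    differential methylation between two groups with a negative-binomial
    exact conditional test (TMM between-sample normalization and
    quantile-adjusted conditional-likelihood dispersion estimation),
    merges adjacent significant windows into differential DNA methylation
    regions (DMRs), annotates DMRs with CpG density and nearby genes,
    compares DMR sets across cohorts at strict and relaxed thresholds, and
    summarizes samples by principal component analysis. A synthetic-data
    module generates genomes, cohorts and fragment data with known injected
    DMRs so the full pipeline is testable without sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    cluster,
    edgeR,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
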