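Package: adlmotif
Title: Upstream Regulatory Motif Scanning and Gene-Set Statistics for
    Neuronal Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the regulatory-genomics analysis of cell-type
    transcriptomes in C. elegans: strand-aware extraction of upstream
    regulatory regions from a genome and annotation, compilation and
    scanning of degenerate gapped DNA motifs (DAF-3/SMAD site, the ~30-bp
    "MSP motif" conserved sequence, composite PD motif, E-box variants),
    RPKM-based expressed-gene calling, gene-set overlap and log-space
    hypergeometric enrichment statistics with extreme-tail support,
    condition-dependence partitioning of differentially expressed gene
    sets, behavioral assay indices (octanol avoidance, chemotaxis,
    reversal fraction), and a synthetic-data generator with truth labels
    so every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
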