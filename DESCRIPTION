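Package: cephoscope
Title: Comparative Homology Inference for Cephalopod Eye Transcriptomes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative homology analysis of developing-eye transcriptomes
    from Nautilus (pinhole eye) and pygmy squid (camera-type eye).
    Assembled transcript contigs are classified by translated best-hit
    search against human and fly reference proteomes, filtered by
    normalized average coverage, tested for Gene Ontology term
    over-representation, and screened for gene-duplication and
    differential-selection events with same-region and conservation
    evidence; candidate gene sets are summarized with Kimura-corrected
    protein distances and neighbor-joining trees. A synthetic
    four-lineage sequence simulator with planted, recoverable events and
    a machine-readable truth ledger supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    ape,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: NCBI BLAST+ (makeblastdb, blastx on PATH)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
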