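Package: spikepause
Title: Spike-In Normalized Analysis of Pol II Pausing from Nascent Transcription
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of immediate transcriptional responses to chromatin
    perturbations from PRO-seq-style single-base 3' end counts: spike-in
    size factors and negative-binomial Wald differential testing of gene-body
    windows, pausing-index computation and its change under treatment,
    TSS-anchored metagene profiles with paired window tests, differential
    ChIP/ATAC peak strength on merged blacklist-filtered peaks, chromatin
    feature z-scores, acetylation-transcription coupling, and qPCR
    (delta-delta Ct and ChIP background/H3 normalization) arithmetic.
    Includes a ground-truthed simulator of paused transcription with
    constant-abundance spike-ins, so the whole pipeline is testable without
    external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
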