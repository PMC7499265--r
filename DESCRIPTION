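Package: isoforge
Title: Long-Read Transcriptome Annotation, Splicing and Duplication-Age
    Analysis with Planted-Truth Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for hybrid long-read/short-read transcriptome studies:
    classification of single-molecule long reads into full-length
    non-chimeric (FLNC) and related classes from primer and poly(A)
    structure, intron-chain collapse of redundant isoform models with
    N50/Ex90N50 completeness statistics, long-read-driven annotation
    refinement (split-gene merge proposals, novel-isoform triage, two
    channel lncRNA calling), five-type alternative-splicing event
    enumeration, Nei-Gojobori (NG86) Ka/Ks estimation with Ks-peak
    detection and whole-genome-duplication dating, and TPM/FPKM
    expression summaries. A deterministic synthetic-data generator with
    machine-readable planted truth makes every stage testable end to end
    without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
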