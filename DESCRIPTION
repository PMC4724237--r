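Package: rtarch
Title: Replication Timing and Nuclear Architecture Analysis
Version: 1.0.0
Authors@R: person("rtarch", "developers", role = c("aut", "cre"),
    email = "rtarch@example.org")
Description: Links DNA replication timing (RT) to nuclear architecture at
    desk scale. Computes binned RT profiles (log2 early/late), smooths and
    segments them into early/late domains, and classifies RT switches
    between genotypes. Calls broad occupancy domains (RAD/LAD style) from
    ChIP enrichment tracks with a permutation-calibrated maximal-segment
    caller, and performs base-pair interval algebra (Venn overlaps, Lamin
    co-occupancy partition, late-genome coverage). Builds scaled meta-domain
    and point-centered signal matrices with k-means clustering, scans
    sequence for GC content, CpG observed/expected ratio, G-quadruplex and
    G-rich origin motifs, and analyses 4C-seq viewpoint contacts (in-silico
    digestion, RPM normalisation, replicate-consistent contact calling,
    RPM-range genotype comparison, intra/inter-RT-domain and TAD-level RT
    specificity). A seeded synthetic-genome simulator with a planted-truth
    record makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    stats,
    utils,
    graphics,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
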