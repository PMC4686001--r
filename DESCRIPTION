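Package: chipconcord
Title: Replicate Concordance Assessment for ChIP-seq Peak Lists
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies ChIP-seq conditions with replicate experiments into
    similar, sensitive and dissimilar categories from peak-list overlap,
    quantifies ChIP enrichment (peak FPKM, FRiP, mean coverage profiles) at
    common, sample-specific and undetected peaks, annotates peaks with
    signed distance to the closest transcription start site, tests
    differential binding between replicates with MA normalization, and
    clusters experiments by binary peak occupancy. Ships a seeded
    synthetic-data generator that emulates replicate narrowPeak lists and
    fragment positions with known ground truth, so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
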