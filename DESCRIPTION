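Package: cryptorf
Title: Detection and Classification of Cryptic Insertion Elements and
    Hidden Out-of-Frame ORFs in Phage Genes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Locates in-phase insertion elements in phage coding genes by
    comparing invaded and uninvaded homologs, tests each element against
    intein and self-splicing-intron sequence signatures, scans all six
    reading frames of the insertion for hidden open reading frames
    (including non-canonical GTG/TTG starts), annotates HNH endonuclease
    and zinc-finger motifs in alternate-frame products, and emits a
    rule-based classification with a full evidence trail.  Ships a
    seed-deterministic synthetic-data generator that plants elements of
    known class and layout with ground-truth coordinates, so every
    pipeline stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    GenomicRanges,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
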