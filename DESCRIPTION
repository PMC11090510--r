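Package: coconutscan
Title: Detection and Classification of McrBC-Family Type IV Restriction
    Systems and CoCoNuT Operons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for the computational census and
    classification of McrBC-family Type IV restriction systems from
    annotated prokaryotic genomes. Implements genomic-neighborhood
    candidate identification with multi-tier alias filtering, McrB/McrC
    operon pairing, signature-motif scanning (Nx(xx)D GTPase motif, HEPN
    RxxxxH/RxH, MIDAS, CPxC), a heptad-propensity coiled-coil heuristic,
    iterative profile clustering with representative selection, a
    rule-based type/subtype classification grammar for coiled-coil
    nuclease tandem (CoCoNuT) systems including TerY-P, extended Type
    III-A and CARF/RtcR superoperon detection, and a synthetic-genome
    generator with planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
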