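Package: crestscan
Title: Topology-Anchored Motif Scanning for Seven-Transmembrane CREST Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens membrane proteins for the CREST superfamily motif
    constellation (SxxxH at the end of transmembrane segment 2, a conserved
    aspartate at the start of segment 3, HxxxH at the start of segment 7)
    using a topology-anchored scan over predicted transmembrane segments,
    together with the naive whole-sequence SxxxHx(100,10000)HxxxH pattern
    baseline, Kyte-Doolittle hydropathy-based transmembrane prediction,
    CD-HIT-style identity de-duplication and coverage-based grouping, and a
    labelled synthetic membrane-proteome generator that plants or
    systematically violates the constellation so every stage of the pipeline
    is verifiable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
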