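Package: sharkid
Title: Mini-DNA-Barcode Identification of CITES-Listed Sharks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for identifying shark products from short (~110-130 bp)
    cytochrome c oxidase I (COI) mini-barcode sequences, as used in wildlife
    forensics and CITES trade enforcement. Provides in-silico PCR with the
    mini-barcode primer cocktail, IUPAC-aware per-species consensus calling,
    construction of compound character attribute (cCA) diagnostic keys that
    separate CITES-listed shark species from their closest relatives, a
    two-track identification strategy combining a local reference-library
    identity search with cCA confirmation, reference-library quality
    screening for probable misidentifications, and a synthetic-data generator
    so the whole pipeline is testable without any database download.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
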