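Package: barcodeval
Title: Species Discrimination Analysis for Plant DNA Barcodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates the species-discrimination power of plant DNA barcode
    markers (such as rbcL and the trnH-psbA spacer) from pre-aligned multi-FASTA
    alignments and a sample-metadata table. Implements exact-identity haplotype
    clustering with the shared-haplotype discrimination rule, uncorrected
    p-distance matrices with per-species barcoding-gap summaries, detection of
    species-diagnostic indels, deterministic best-match identification against a
    local reference library with leave-one-out evaluation, and a cross-method
    summary of identification success. A seeded simulator generates aligned
    multi-genus barcode communities with controllable intraspecific and
    interspecific divergence, haplotype sharing, fixed indels and reference
    library incompleteness, so every stage can be tested without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
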