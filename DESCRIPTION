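Package: barcodiag
Title: DNA Barcode Distances, Barcoding-Gap Delimitation and Character-Based Species Diagnosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for species-level analysis of aligned DNA barcodes (COI-style
    markers on the standard 658 bp reference frame): pairwise genetic distances
    under nested substitution models (p, JC69, K2P, TN93) with optional gamma
    rate correction and pairwise deletion; within- and among-species distance
    summaries; barcoding-gap statistics and threshold-based OTU clustering with
    delimitation rules combining divergence thresholds with morphological
    evidence; and character-based DNA diagnoses listing unique and partially
    shared diagnostic substitutions with combination verification. Includes a
    seeded simulator of species-structured barcode alignments with planted
    diagnostic sites for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
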