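Package: genusprimer
Title: Genus-Specific 16S rRNA Primer Design, In-Silico PCR and Amplicon
    Read Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A dry-lab toolkit for designing and validating genus-specific
    PCR primer pairs from 16S rRNA gene panels. Computes per-column
    conservation profiles over in-group alignments, enumerates primer
    candidates inside conserved windows, scores genus specificity against
    an out-group under a mismatch-tolerant binding model with a 3' clamp,
    predicts amplicons by in-silico PCR, and quantifies genus detection in
    amplicon read sets via best-hit identity classification and an
    effective amplification rate. Includes nearest-neighbor melting
    temperature calculations and a seeded generator of 16S-like sequence
    families with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    S4Vectors,
    seqinr,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
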