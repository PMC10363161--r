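Package: azfcnv
Title: Read-Depth Detection of Y Chromosome AZFb/c Structural Rearrangements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects copy-number variants of the ampliconic AZFb/c region of
    the human Y chromosome from whole-genome sequencing read depth. Per-base
    depth over amplicon families is averaged over repeat-masked positions,
    normalised by a ~900 kb single-copy control region, and converted to
    integer amplicon copy numbers by midpoint thresholds between expected
    dosage ratios. Calls are confirmed with a normalised exponential
    moving-average depth profile, interpreted as sequences of non-allelic
    homologous recombination (NAHR) events (duplications, deletions,
    inversions) on an ordered amplicon structure, and summarised at cohort
    level with carrier incidences and Fisher exact comparisons. A seeded
    Poisson/negative-binomial coverage simulator with known copy-number truth
    supports end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
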