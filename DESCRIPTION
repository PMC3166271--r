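Package: swlane
Title: Score-Only Smith-Waterman Protein Database Search over Lane-Packed Databases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts protein FASTA databases into a sorted, concatenated,
    interlaced equal-length packed layout designed for 16-lane lock-step
    execution, and streams that layout through a score-only Smith-Waterman
    engine with affine gap penalties (Gotoh recurrences) and a per-query
    substitution profile. Includes a full-matrix scalar scoring oracle, a
    top-hit reporter with FASTA export for downstream full alignment, an
    analytic memory-access cost model (transaction coalescing, temporary-data
    bandwidth ladder, profile cache capacity, workload balance), and a seeded
    synthetic protein database generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
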