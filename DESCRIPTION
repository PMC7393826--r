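Package: rearrangekit
Title: Detection and Full Reconstruction of Complex Germline Rearrangements
    from Long DNA Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for finding, filtering, and fully
    reconstructing complex germline chromosomal rearrangements (including
    chromothripsis) from noisy long DNA reads.  It learns substitution and
    indel rates between reads and a reference genome, performs probability
    based split alignment with per-segment mismap probabilities, extracts
    rearrangement junctions, subtracts rearrangements shared with control
    individuals, groups corroborating reads, merges each group into a
    consensus sequence that tightens breakpoints to base precision, links
    the groups by parsimony into a minimal number of derivative
    chromosomes, and reports emergent sequence losses and gains that are
    visible only after full reconstruction.  A bundled simulator generates
    synthetic references, rearrangement operations, noisy reads, and
    control cohorts with ground-truth junctions for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    igraph,
    jsonlite,
    stats,
    utils,
    methods,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
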