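Package: tandemscan
Title: Annotation-Free Detection of Long Tandem Duplications in Genomic
    Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects long, possibly degenerate tandem duplications directly
    from genomic DNA, without gene annotation. Local self-alignment anchors
    are chained into colinear, mutually non-overlapping tandem chains by a
    successive-shortest-path minimum-cost flow on an anchor DAG; overlapping
    chains are grouped into tandem arrays; a reference duplication unit is
    extracted per array by iterative self-similarity trimming, and the array
    is re-searched with the unit (translated or nucleotide mode) to call the
    individual tandem units. Includes a planted-array genome simulator and
    an evaluation layer scoring predictions against annotation-derived
    tandem gene arrays.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    jsonlite,
    withr,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
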