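Package: tandemdup
Title: Split-Read Detection of Tandem Duplications by Pattern Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects tandem duplications (10 bp to multi-kb) at single
    nucleotide breakpoint resolution from coordinate-sorted short-read
    alignments. Read pairs with one uniquely mapped anchor and a
    soft-clipped or unmapped mate are analysed with a pattern growth
    search for minimum and maximum unique substrings, followed by
    size-stratified breakpoint reconstruction, support filtering and
    redundancy merging. Includes a wgsim-style paired-end read simulator,
    an aligner-free alignment emulator for exact ground-truth testing,
    and interval-matching evaluation utilities (precision, recall, F1,
    FDR) against planted truth sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Rsamtools,
    Biostrings,
    IRanges,
    S4Vectors,
    data.table,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
SystemRequirements: Optionally bwa and samtools on the PATH for the
    aligner-based benchmark pipeline.
Config/testthat/edition: 3
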