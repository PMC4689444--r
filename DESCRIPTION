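Package: gssr
Title: Genome Survey Sequencing Characterization and Microsatellite
    Marker Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to characterize a genome from low-coverage paired-end
    shotgun sequencing ("genome survey sequencing") and to mine it for
    microsatellite markers. Read pairs from short-insert libraries are
    quality- and adapter-trimmed, screened for orientation artifacts, and
    merged into reconstructed fragments; fragments are profiled for GC
    content, sequencing depth, repeat-element content and gene-likeness;
    perfect 2-4 bp microsatellites are mined under copy-number windows,
    grouped into canonical motif classes, and turned into potentially
    amplifiable loci (PALs) by exhaustive constraint-based primer design
    with nearest-neighbor melting temperatures and low-complexity
    masking. Flow-cytometry peak ratios against internal standards are
    converted to 2C DNA amounts and genome sizes in Mbp. A synthetic-data
    generator produces genomes with planted repeats, retroelement-like
    insertions and gene fragments, plus realistic overlapping read pairs,
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    stringi,
    readr,
    ggplot2,
    generics,
    withr,
    data.table,
    Biostrings,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
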