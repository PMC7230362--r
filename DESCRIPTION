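Package: nanobarcode
Title: Amplicon DNA Barcoding Consensus from Noisy Long Reads
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for species identification by amplicon
    DNA barcoding on error-prone long reads (nanopore-style). Implements
    dual-index demultiplexing in two modes (alignment-score based and
    edit-distance based), quality and length filtering of reads, seeded
    subsampling, strand-aware greedy minimizer clustering, partial order
    alignment (POA) consensus generation, reverse-complement-aware consensus
    merging, majority-cluster selection, pileup majority polishing, primer
    trimming, and percent-identity reporting against reference barcodes.
    Includes a read simulator with a homopolymer-biased error model so the
    whole pipeline can be exercised and validated at desk scale without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
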