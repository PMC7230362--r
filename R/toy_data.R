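# Bundled synthetic references. Real barcode sequences live in public
# archives as accessions; for a self-contained toolkit we ship two synthetic
# 421-bp inserts (~71% mutual identity, i.e. comfortably below the 0.9
# consensus-merge cutoff and below the 80% bound used in tests), a synthetic
# primer pair, and a panel of four synthetic 24-nt dual-index pairs whose
# mutual edit distances are >= 12. All were drawn once from a fixed seed and
# frozen here so every example and test sees identical inputs.

.toy_insert_a <- paste0(
  "CCCTCGGATTCCAGACGGCAGATAAACGACTGGAACCTTTCGGGGGAAGAAAAAATCCCTGTGACCGGTT",
  "TAAGTCTTTGCCTAATTTAGCCAAGGACAATCGGTGCGCACTTTCTGATTTTTTTCCGGCTCCTAACACT",
  "AGAATAAGTATGCGCTCCACACCTGAAGGGACGCGGGTACTACTGTACTTTCTTCTAGGGGGGGGGCGGT",
  "CCGGCTGAAGTATGGCTCGCGACGTGGATCTAAAGACAATAGACCGATCTTTAAGGTGCTTCCGTTAGCC",
  "CCCCAGGGGCTGGTGAAGGGTCCGGCGCGCTGGCTATGATCAGCAAACTTTTCACTGTACAGTGCTAGTA",
  "AAAAATGCATCGTGAATAATTTCGGTAGCACCTCCAGTCCTGTACACAACACCAGGACTCTCACGCGAGGC")

.toy_insert_b <- paste0(
  "CCCTCGGATTTCAGGTAGCGAGCGGACAATTGGAGTCTTTCGGGGAAAGAAAAAGCCCTTGTGACCAGTT",
  "TGAGTCTTCGCTCGGCCTGACCAAGGACGGTTGACGCGTACTTCCTAATTTTCTTCTGACCCCCAATACT",
  "GAGATAAGTATACGTTTCATGCTTAAAGGGATATGAGTGCTATTACACTCTCTTTCAGAGGGGAGGCGGT",
  "CCAACTAGAGCGCGACTCACAGCGTGGATCCAAAGACGACAGACCAATCCTCAAGGTGCTTCTACTAGCC",
  "CCTTAGGAGCTGATGAGGAGTTTAACGCGCTAACTACAATTAGCAGACTTCTCACTATATAGTATTAATG",
  "AGAAATGTATCGTGAATGGTTTCAATAGCACCTCTAGTTCCGCGCGCGATATTAGGACTCTCACACAAGGC")

.toy_fwd_primer <- "AACTTAAATGTGGCACACCTCGTGA"
.toy_rev_primer <- "TTGTCAAGTGGCCCATCCGCCCCGCA"

.toy_indexes <- c(
  "GCGGGCCTTATAATCATGTTATGT", "CCTTAAATTCGGACGGCGCGGTAC",
  "AGCTAGGAGTTGACCCTCTAAGTT", "AGACCCCTCAAACAGGGGAAGCTG",
  "AGTGAAAAATAACTTAGACGACAG", "AACGCCTCGTCTTGTAGTCGAGGC",
  "GTCATCCGATAACGCCTGACATAG", "GAACCGTTAAGCTTATCCGGGCCA")

#' Bundled synthetic barcode inserts
#'
#' Two synthetic 421-bp target inserts standing in for the mitochondrial
#' cytochrome b barcodes of two distinct species (about 71% mutual identity,
#' so reads from the two never co-cluster). Insert A carries several planted
#' homopolymer runs (5-7 nt) so the homopolymer-biased error model and the
#' polishing stage are exercised on it.
#'
#' @return A [reference_set()] with inserts `"speciesA"` and `"speciesB"`.
#' @examples
#' nchar(toy_inserts()$bases)  # 421 421
#' @export
toy_inserts <- function() {
  reference_set(c("speciesA", "speciesB"), c(.toy_insert_a, .toy_insert_b))
}

#' Bundled synthetic primer pair
#'
#' @return A [reference_set()] with `role = "primer"`: a 25-nt forward and a
#'   26-nt reverse primer. As everywhere in this package, the reverse primer
#'   is given 5'->3' on its own strand; on the forward strand of the amplicon
#'   it appears reverse-complemented at the 3' end.
#' @export
toy_primers <- function() {
  reference_set(c("fwd_primer", "rev_primer"),
                c(.toy_fwd_primer, .toy_rev_primer), role = "primer")
}

#' Bundled synthetic dual-index panel
#'
#' Four sample index pairs of 24-nt synthetic indexes (all pairwise edit
#' distances >= 12), in the tabular form the demultiplexer consumes.
#'
#' @param n number of pairs to return (1-4).
#' @return A data frame with columns `sample_label`, `forward_index`,
#'   `reverse_index`.
#' @export
toy_index_panel <- function(n = 4) {
  stopifnot(n >= 1, n <= 4)
  out <- data.frame(
    sample_label = paste0("sample", seq_len(4)),
    forward_index = .toy_indexes[c(1, 3, 5, 7)],
    reverse_index = .toy_indexes[c(2, 4, 6, 8)],
    stringsAsFactors = FALSE)
  out[seq_len(n), , drop = FALSE]
}
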