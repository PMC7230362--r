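#' Trim primers from a consensus sequence
#'
#' Locates the forward primer near the 5' end and the reverse-complemented
#' reverse primer near the 3' end (semi-global alignment, up to `max_edits`
#' differences each), removing the primers and everything outside them. Both
#' consensus orientations are tried and the one with more primer hits wins.
#' An end whose primer cannot be located is left untouched and flagged --
#' a consensus built from already primer-trimmed reads simply comes back
#' unchanged.
#'
#' @param consensus DNA string.
#' @param fwd_primer,rev_primer primer sequences, 5'->3' on their own
#'   strands.
#' @param max_edits maximum edit distance for a primer hit.
#' @return A list: `consensus` (trimmed, returned in the orientation in
#'   which the primers were located), `trimmed_fwd`, `trimmed_rev` (logical
#'   flags), `orientation` (`"as_is"` or `"rc"` of the input).
#' @export
trim_primers <- function(consensus, fwd_primer, rev_primer, max_edits = 11) {
  stopifnot(nchar(consensus) > 0)
  fwd_primer <- toupper(fwd_primer)
  rev_primer <- toupper(rev_primer)
  # a retained primer can only sit flush at the consensus end, so the search
  # is anchored there: a short window and a start (or end) within a few
  # bases of the terminus. An unanchored search with an 11-edit tolerance
  # would "find" a 25-nt primer inside unrelated barcode sequence.
  try_one <- function(bases) {
    L <- nchar(bases)
    rp_rc <- reverse_complement(rev_primer)
    slack <- 8L
    anchor <- 4L
    wf <- min(L, nchar(fwd_primer) + slack)
    hit_f <- semiglobal_fit(fwd_primer, substr(bases, 1L, wf))
    wr_start <- max(1L, L - nchar(rp_rc) - slack + 1L)
    hit_r <- semiglobal_fit(rp_rc, substr(bases, wr_start, L))
    got_f <- hit_f$edits <= max_edits && hit_f$start <= anchor
    got_r <- hit_r$edits <= max_edits &&
      (L - (wr_start - 1L + hit_r$end)) <= anchor
    start <- if (got_f) hit_f$end + 1L else 1L
    end <- if (got_r) wr_start - 1L + hit_r$start else L
    list(bases = if (end >= start) substr(bases, start, end) else "",
         got_f = got_f, got_r = got_r, n_hits = got_f + got_r)
  }
  as_is <- try_one(consensus)
  rc <- try_one(reverse_complement(consensus))
  use_rc <- rc$n_hits > as_is$n_hits
  res <- if (use_rc) rc else as_is
  if (!nchar(res$bases)) {
    warning("primer trimming would remove the whole consensus; returning input")
    return(list(consensus = consensus, trimmed_fwd = FALSE,
                trimmed_rev = FALSE, orientation = "as_is"))
  }
  list(consensus = res$bases, trimmed_fwd = res$got_f, trimmed_rev = res$got_r,
       orientation = if (use_rc) "rc" else "as_is")
}

#' Compare a consensus to reference barcode sequences
#'
#' Exhaustive global pairwise alignment (free end gaps) of the consensus --
#' in both orientations -- against every supplied reference; the best hit by
#' percent identity is reported. Percent identity is `100 * matches /
#' alignment_length` and `matching_length` counts the identical aligned
#' positions, so "421 of 421 bp" means a full-length perfect match.
#'
#' @param consensus DNA string (non-empty).
#' @param references a [reference_set()] or named character vector.
#' @param sample_label optional label carried into the report.
#' @return A one-row data frame: `sample_label`, `best_reference`,
#'   `percent_identity`, `matching_length`, `consensus_length`,
#'   `alignment_length`.
#' @export
identity_to_reference <- function(consensus, references,
                                  sample_label = NA_character_) {
  if (!nchar(consensus)) stop("empty consensus")
  if (is.character(references)) {
    references <- reference_set(names(references), references)
  }
  stopifnot(nrow(references) >= 1)
  rc <- reverse_complement(consensus)
  best <- NULL
  for (i in seq_len(nrow(references))) {
    for (s in c(consensus, rc)) {
      r <- pairwise_identity(s, references$bases[i])
      if (is.null(best) || r$identity > best$identity) {
        best <- r
        best$name <- references$name[i]
      }
    }
  }
  data.frame(sample_label = sample_label,
             best_reference = best$name,
             percent_identity = 100 * best$identity,
             matching_length = best$matches,
             consensus_length = nchar(consensus),
             alignment_length = best$aln_len,
             stringsAsFactors = FALSE)
}

#' Evaluate species-identification acceptance criteria
#'
#' Applies the three-part decision rule for a confident barcode
#' identification: percent identity strictly above `min_identity`, matching
#' length within `length_tol` of the expected insert length, and a
#' sufficient fraction of reads behind the consensus. A fraction below
#' `min_fraction` raises an `investigate` flag (minority clusters may hold
#' contaminant or high-error reads) without failing the identification
#' outright.
#'
#' @param report a row from [identity_to_reference()], with an added
#'   `fraction_reads_clustered` column (the pipeline supplies it).
#' @param min_identity identity threshold in percent (strict).
#' @param expected_length expected insert length in bp.
#' @param length_tol tolerated deviation of `matching_length` in bp.
#' @param min_fraction minimum fraction of reads supporting the consensus.
#' @return The report with logical columns `identity_pass`, `length_pass`,
#'   `fraction_pass`, `investigate`, `pass`.
#' @export
evaluate_criteria <- function(report, min_identity = 99,
                              expected_length = 421, length_tol = 5,
                              min_fraction = 0.75) {
  stopifnot("percent_identity" %in% names(report),
            "matching_length" %in% names(report))
  frac <- if ("fraction_reads_clustered" %in% names(report)) {
    report$fraction_reads_clustered
  } else NA_real_
  report$identity_pass <- report$percent_identity > min_identity
  report$length_pass <- abs(report$matching_length - expected_length) <= length_tol
  report$fraction_pass <- !is.na(frac) & frac >= min_fraction
  report$investigate <- is.na(frac) | frac < min_fraction
  report$pass <- report$identity_pass & report$length_pass
  report
}
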