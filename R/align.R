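#' Locate a short pattern inside a text by semi-global alignment
#'
#' Aligns `pattern` end-to-end against `text` with free gaps at the text ends
#' (unit edit costs), the standard way to find a primer or index inside a
#' read. Ties are broken towards the smallest start, then the smallest end.
#'
#' @param pattern short DNA string (aligned completely).
#' @param text DNA string to search in.
#' @return A list with `edits` (minimal edit distance), and `start`/`end`,
#'   the 0-based half-open span of the pattern's best placement in `text`.
#' @export
semiglobal_fit <- function(pattern, text) {
  r <- cpp_semiglobal_fit(pattern, text)
  list(edits = r[1], start = r[2], end = r[3])
}

#' Percent identity of two sequences under free-end-gap global alignment
#'
#' Identity is `matches / alignment_length` of a global alignment whose end
#' gaps are unpenalised in the score but still counted as alignment columns,
#' mirroring cd-hit-est's global-identity semantics: length disagreement
#' between the two sequences counts against identity.
#'
#' @param a,b DNA strings.
#' @param match,mismatch,gap alignment scores.
#' @return A list with `identity` (in `[0, 1]`), `matches`, `aln_len`,
#'   `score`.
#' @export
pairwise_identity <- function(a, b, match = 2, mismatch = -4, gap = -6) {
  r <- cpp_overlap_align(a, b, match, mismatch, gap)
  list(identity = r$matches / r$aln_len, matches = r$matches,
       aln_len = r$aln_len, score = r$score)
}
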