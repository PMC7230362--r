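#' Validate a dual-index panel
#'
#' A panel maps sample labels to dual index pairs. All index sequences within
#' a panel must be unique and of a common length, so that the score formula
#' and edit thresholds mean the same thing for every sample.
#'
#' @param panel data frame with columns `sample_label`, `forward_index`,
#'   `reverse_index`.
#' @return The validated panel (index sequences uppercased), invisibly usable
#'   downstream.
#' @export
validate_panel <- function(panel) {
  stopifnot(is.data.frame(panel),
            all(c("sample_label", "forward_index", "reverse_index") %in% names(panel)))
  panel$sample_label <- as.character(panel$sample_label)
  panel$forward_index <- toupper(panel$forward_index)
  panel$reverse_index <- toupper(panel$reverse_index)
  if (anyDuplicated(panel$sample_label)) stop("duplicate sample labels in panel")
  idx <- c(panel$forward_index, panel$reverse_index)
  if (anyDuplicated(idx)) stop("index sequences within a panel must be unique")
  if (any(grepl("[^ACGT]", idx))) stop("indexes must be unambiguous A/C/G/T")
  if (length(unique(nchar(idx))) != 1L) {
    stop("all indexes in a panel must have equal length")
  }
  panel
}

#' Locate an index sequence near a read end
#'
#' Searches the first (or last) `search_window` bases of the read for the
#' best semi-global placement of `index`. Absence is signalled by a large
#' edit distance, not an error.
#'
#' @param read a single-row [read_set()] or a DNA string.
#' @param index index sequence to locate.
#' @param search_window number of bases at the read end to search
#'   (>= `nchar(index)`).
#' @param from `"start"` or `"end"`: which read end to search.
#' @return A list with `edits`, `start`, `end` (0-based half-open
#'   coordinates in the full read).
#' @export
locate_index <- function(read, index, search_window = 150, from = "start") {
  bases <- if (inherits(read, "read_set")) read$bases[1] else read
  from <- match.arg(from, c("start", "end"))
  if (search_window < nchar(index)) {
    stop("search_window must be at least the index length")
  }
  L <- nchar(bases)
  w <- min(search_window, L)
  if (from == "start") {
    hit <- semiglobal_fit(index, substr(bases, 1L, w))
  } else {
    off <- L - w
    hit <- semiglobal_fit(index, substr(bases, off + 1L, L))
    hit$start <- hit$start + off
    hit$end <- hit$end + off
  }
  hit
}

# locate both indexes of a pair on an already-oriented read:
# forward_index at the 5' end, rc(reverse_index) at the 3' end
.locate_pair <- function(bases, fwd_index, rev_index_rc, search_window) {
  f <- locate_index(bases, fwd_index, search_window, from = "start")
  r <- locate_index(bases, rev_index_rc, search_window, from = "end")
  list(f = f, r = r)
}

#' Demultiplex reads by dual index pairs
#'
#' Assigns each read to at most one sample, orients it so the forward index
#' sits at the 5' end, and trims the located index (and, in edit mode, the
#' primer) sequence. Two modes are provided:
#'
#' * `"score"` (qcat-like): per index, `score = 100 * (index_length -
#'   edit_distance) / index_length`; the pair score is the worse of the two
#'   indexes and both must be found. Assignment requires `score >=
#'   min_score`; at the default `min_score = 99` a 24-nt index must match
#'   exactly. Indexes are trimmed; primers are retained.
#' * `"edit"` (MiniBar-like): assignment requires both indexes within
#'   `max_index_edits`. Primers found within `max_primer_edits` just inside
#'   the indexes are trimmed as well; an unlocatable primer is retained
#'   (under-trimming is preferred over cutting into the barcode).
#'
#' In both modes a tie between two index pairs leaves the read `UNASSIGNED`
#' (ambiguous), so assigned reads form a partition: no read can reach two
#' samples.
#'
#' @param reads a [read_set()].
#' @param panel index panel (see [validate_panel()]).
#' @param mode `"score"` or `"edit"`.
#' @param primers a `reference_set` with roles `primer`, or a character
#'   vector `c(forward, reverse)`; required for edit mode.
#' @param min_score score-mode assignment threshold (percent).
#' @param max_index_edits,max_primer_edits edit-mode thresholds.
#' @param search_window bases searched at each read end.
#' @return A list with `assignments` (one row per read: `read_id`,
#'   `sample_label` (`NA` = unassigned), `mode`, `score`, `edits_fwd`,
#'   `edits_rev`, `strand`, `trim_start`, `trim_end` -- 0-based half-open
#'   coordinates in the oriented read) and `samples` (a named list of
#'   trimmed, forward-oriented [read_set()]s, one per assigned sample).
#' @export
demux_reads <- function(reads, panel, mode = c("edit", "score"),
                        primers = NULL, min_score = 99,
                        max_index_edits = 2, max_primer_edits = 11,
                        search_window = 150) {
  mode <- match.arg(mode)
  panel <- validate_panel(panel)
  if (nrow(panel) == 0L) stop("index panel is empty")
  if (mode == "edit") {
    if (is.null(primers)) stop("edit mode requires primer sequences")
    primers <- .as_primer_pair(primers)
  }
  idx_len <- nchar(panel$forward_index[1])
  rev_rc <- reverse_complement(panel$reverse_index)

  n <- nrow(reads)
  sample_label <- rep(NA_character_, n)
  score <- rep(NA_real_, n)
  ef <- er <- rep(NA_integer_, n)
  strand <- rep(NA_character_, n)
  ts <- te <- rep(NA_integer_, n)
  oriented <- reads$bases
  oriented_q <- reads$quals

  for (i in seq_len(n)) {
    fw_b <- reads$bases[i]
    rc_b <- reverse_complement(fw_b)
    # best placement per pair (better of the two orientations; forward on tie)
    cands <- vector("list", nrow(panel))
    for (p in seq_len(nrow(panel))) {
      for (orient in c("forward", "reverse")) {
        b <- if (orient == "forward") fw_b else rc_b
        hits <- .locate_pair(b, panel$forward_index[p], rev_rc[p], search_window)
        cand <- list(pair = p, orient = orient, hits = hits,
                     edits = hits$f$edits + hits$r$edits,
                     worst = max(hits$f$edits, hits$r$edits))
        if (is.null(cands[[p]]) ||
            cand$worst < cands[[p]]$worst ||
            (cand$worst == cands[[p]]$worst && cand$edits < cands[[p]]$edits)) {
          cands[[p]] <- cand
        }
      }
    }
    # best pair under the mode's metric; a cross-pair tie means ambiguity
    metric <- vapply(cands, function(cc)
      if (mode == "score") cc$worst else cc$edits, numeric(1))
    p_best <- which.min(metric)
    tie <- sum(metric == metric[p_best]) > 1L
    best <- cands[[p_best]]
    pair_score <- 100 * (idx_len - best$worst) / idx_len
    qualifies <- if (mode == "score") pair_score >= min_score else
      best$hits$f$edits <= max_index_edits && best$hits$r$edits <= max_index_edits
    if (!qualifies || tie) next

    b <- if (best$orient == "forward") fw_b else rc_b
    q <- if (best$orient == "forward") reads$quals[i] else
      intToUtf8(rev(utf8ToInt(reads$quals[i])))
    t0 <- best$hits$f$end
    t1 <- best$hits$r$start
    if (t1 <= t0) next  # indexes overlap: geometry is broken, leave unassigned
    if (mode == "edit") {
      tr <- .trim_primers_inside(b, t0, t1, primers, max_primer_edits)
      t0 <- tr[1]; t1 <- tr[2]
      if (t1 <= t0) next
    }
    sample_label[i] <- panel$sample_label[best$pair]
    score[i] <- pair_score
    ef[i] <- best$hits$f$edits
    er[i] <- best$hits$r$edits
    strand[i] <- best$orient
    ts[i] <- t0
    te[i] <- t1
    oriented[i] <- substr(b, t0 + 1L, t1)
    oriented_q[i] <- substr(q, t0 + 1L, t1)
  }

  assignments <- data.frame(
    read_id = reads$read_id, sample_label = sample_label, mode = mode,
    score = score, edits_fwd = ef, edits_rev = er, strand = strand,
    trim_start = ts, trim_end = te, stringsAsFactors = FALSE)

  samples <- list()
  for (s in panel$sample_label) {
    sel <- which(!is.na(sample_label) & sample_label == s)
    if (!length(sel)) next
    samples[[s]] <- read_set(reads$read_id[sel], oriented[sel],
                             oriented_q[sel], orientation = "forward")
  }
  list(assignments = assignments, samples = samples)
}

.as_primer_pair <- function(primers) {
  if (inherits(primers, "reference_set") || is.data.frame(primers)) {
    p <- primers$bases
  } else {
    p <- toupper(primers)
  }
  if (length(p) != 2L) stop("expected exactly a forward and a reverse primer")
  p
}

# trim primers just inside located indexes; retain a primer that cannot be
# located within max_edits (under-trimming tolerated by design)
.trim_primers_inside <- function(bases, t0, t1, primers, max_edits) {
  fp <- primers[1]
  rp_rc <- reverse_complement(primers[2])
  slack <- 8L
  anchor <- 4L  # the primer sits flush against the index it follows
  w_end <- min(nchar(bases), t0 + nchar(fp) + slack)
  if (w_end > t0) {
    hit <- semiglobal_fit(fp, substr(bases, t0 + 1L, w_end))
    if (hit$edits <= max_edits && hit$start <= anchor) t0 <- t0 + hit$end
  }
  w_start <- max(1L, t1 - nchar(rp_rc) - slack + 1L)
  if (t1 >= w_start) {
    hit <- semiglobal_fit(rp_rc, substr(bases, w_start, t1))
    if (hit$edits <= max_edits && (t1 - (w_start - 1L + hit$end)) <= anchor) {
      t1 <- w_start - 1L + hit$start
    }
  }
  c(t0, t1)
}

#' Summarise demultiplexing assignments
#'
#' @param assignments the `assignments` data frame from [demux_reads()].
#' @return A data frame with reads per sample (including `UNASSIGNED`) and
#'   the percentage of total reads.
#' @export
demux_summary <- function(assignments) {
  lab <- ifelse(is.na(assignments$sample_label), "UNASSIGNED",
                assignments$sample_label)
  tab <- table(lab)
  data.frame(sample_label = names(tab), n_reads = as.integer(tab),
             pct_reads = round(100 * as.integer(tab) / nrow(assignments), 2),
             stringsAsFactors = FALSE, row.names = NULL)
}
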