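#' Filtering thresholds for demultiplexed reads
#'
#' Defaults follow the usual amplicon practice for a 421-bp target: drop
#' reads with mean Phred quality below 7 and keep only lengths inside a
#' 100-bp buffer around the target (321-521 bp, bounds inclusive). Lengths
#' are measured after demultiplexing/trimming.
#'
#' @param min_mean_q minimum mean read quality (Phred).
#' @param min_len,max_len inclusive length window in bp.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_mean_q = 7, min_len = 321, max_len = 521) {
  stopifnot(min_len <= max_len, min_mean_q >= 0)
  structure(list(min_mean_q = min_mean_q, min_len = min_len,
                 max_len = max_len), class = "filter_config")
}

#' Mean read quality (error-probability average)
#'
#' The mean quality of a read is computed on the error-probability scale,
#' `Q = -10 log10( mean_i 10^(-q_i / 10) )`, not as the arithmetic mean of
#' the per-base Phred values. The two differ whenever qualities vary within
#' a read, and the error-probability mean is the quantity a quality filter
#' should act on (it is what the read's expected accuracy actually is).
#'
#' @param reads a [read_set()]; all reads must be non-empty.
#' @return Numeric vector of mean qualities, one per read.
#' @examples
#' r <- read_set("r1", "ACGT", list(c(10L, 10L, 20L, 20L)))
#' mean_read_quality(r)  # 12.596 rather than 15
#' @export
mean_read_quality <- function(reads) {
  if (any(!nchar(reads$bases))) stop("mean quality of an empty read is undefined")
  vapply(reads$quals, function(s) {
    q <- utf8ToInt(s) - 33L
    -10 * log10(mean(10^(-q / 10)))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Filter reads on mean quality and length
#'
#' A read is retained iff its mean quality (see [mean_read_quality()]) is at
#' least `min_mean_q` and its length lies inside `[min_len, max_len]`
#' (inclusive). Filtering is idempotent.
#'
#' @param reads a [read_set()] (typically demultiplexed and trimmed).
#' @param cfg a [filter_config()].
#' @return A list with `retained` (a [read_set()]) and `rejected` (a data
#'   frame `read_id`, `length`, `mean_quality`, `reason`).
#' @export
filter_reads <- function(reads, cfg = filter_config()) {
  if (!nrow(reads)) {
    return(list(retained = reads,
                rejected = data.frame(read_id = character(0),
                                      length = integer(0),
                                      mean_quality = numeric(0),
                                      reason = character(0))))
  }
  len <- nchar(reads$bases)
  q <- mean_read_quality(reads)
  too_short <- len < cfg$min_len
  too_long <- len > cfg$max_len
  low_q <- q < cfg$min_mean_q
  keep <- !(too_short | too_long | low_q)
  reason <- character(nrow(reads))
  reason[low_q] <- "low_quality"
  reason[too_short] <- "too_short"   # length reasons take precedence in the log
  reason[too_long] <- "too_long"
  rejected <- data.frame(read_id = reads$read_id[!keep],
                         length = len[!keep],
                         mean_quality = round(q[!keep], 3),
                         reason = reason[!keep],
                         stringsAsFactors = FALSE)
  list(retained = reads[keep, ], rejected = rejected)
}

#' Seeded random read subset
#'
#' Uniform sampling without replacement of `min(k, n)` reads; input order is
#' preserved in the output. Requesting more reads than available returns all
#' reads with a warning.
#'
#' @param reads a [read_set()].
#' @param k target subset size.
#' @param seed integer seed; the same seed always yields the same subset.
#' @return A [read_set()].
#' @export
subset_reads <- function(reads, k, seed = NULL) {
  stopifnot(k >= 1)
  n <- nrow(reads)
  if (k >= n) {
    if (k > n) warning("requested ", k, " reads but only ", n, " available")
    return(reads)
  }
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  sel <- sort(sample(n, k))
  reads[sel, ]
}

#' Per-stage run statistics
#'
#' Summarises read counts, mean length and mean quality across pipeline
#' stages (e.g. raw, demultiplexed, filtered, subset), with stage-to-stage
#' retention percentages.
#'
#' @param stages a named list of [read_set()]s, in pipeline order.
#' @return A data frame with one row per stage: `stage`, `n_reads`,
#'   `mean_length`, `mean_quality`, `pct_of_previous`.
#' @export
compute_stats <- function(stages) {
  stopifnot(is.list(stages), length(names(stages)) == length(stages))
  rows <- lapply(seq_along(stages), function(i) {
    rs <- stages[[i]]
    n <- nrow(rs)
    data.frame(
      stage = names(stages)[i],
      n_reads = n,
      mean_length = if (n) mean(nchar(rs$bases)) else NA_real_,
      mean_quality = if (n) mean(mean_read_quality(rs)) else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  prev <- c(NA, out$n_reads[-nrow(out)])
  out$pct_of_previous <- ifelse(is.na(prev) | prev == 0, NA_real_,
                                round(100 * out$n_reads / prev, 2))
  out
}
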