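#' Clustering parameters
#'
#' Greedy, quality-ordered, strand-aware minimizer clustering in the
#' isONclust tradition. A read joins a cluster when a sufficient fraction of
#' its minimizers is found in the cluster's minimizer profile (the union of
#' minimizers contributed by its members). The joining threshold is set from
#' the error model rather than guessed: at per-base error rate `e`, a k-mer
#' survives uncorrupted in a read with probability about `(1-e)^k`
#' (`0.91^13 ~ 0.29` at the ~9% error typical of the reads this package
#' targets), so same-template reads share roughly that fraction of
#' minimizers with a saturated profile, while templates at <= 80% identity
#' share `~0.8^13 * 0.29 ~ 0.016`. The default threshold 0.07 is the
#' geometric midpoint of those two regimes.
#'
#' @param kmer_size minimizer k-mer length (>= 7).
#' @param window_size number of consecutive k-mers per minimizer window.
#' @param min_shared_fraction minimum fraction of a read's minimizers that
#'   must be present in a cluster profile for the read to join.
#' @param min_cluster_fraction retention gate: keep clusters with strictly
#'   more than this fraction of the clustered reads.
#' @param profile_max_reads profile saturation: only the first this-many
#'   members add their minimizers to the cluster profile.
#' @param refine run the absorption pass (see [greedy_cluster()]).
#' @return A list of class `cluster_config`.
#' @export
cluster_config <- function(kmer_size = 13, window_size = 5,
                           min_shared_fraction = 0.07,
                           min_cluster_fraction = 0.10,
                           profile_max_reads = 100, refine = TRUE) {
  stopifnot(kmer_size >= 7, window_size >= 1,
            min_shared_fraction > 0, min_shared_fraction < 1,
            min_cluster_fraction > 0, min_cluster_fraction < 1)
  structure(list(kmer_size = kmer_size, window_size = window_size,
                 min_shared_fraction = min_shared_fraction,
                 min_cluster_fraction = min_cluster_fraction,
                 profile_max_reads = profile_max_reads, refine = refine),
            class = "cluster_config")
}

#' Minimizer sketch of a sequence
#'
#' The lexicographically smallest k-mer of each sliding window of `w`
#' consecutive k-mers, with ties resolved to the leftmost position.
#' Identical strings always produce identical sketches; a sequence shorter
#' than `k` has an empty sketch.
#'
#' @param bases a single DNA string.
#' @param k k-mer length.
#' @param w window size in k-mers.
#' @return A data frame with columns `minimizer` and `pos` (1-based start of
#'   the minimizer k-mer), one row per distinct (minimizer, position) pair,
#'   in sequence order.
#' @export
minimizer_sketch <- function(bases, k = 13, w = 5) {
  n <- nchar(bases)
  if (n < k) {
    return(data.frame(minimizer = character(0), pos = integer(0)))
  }
  starts <- seq_len(n - k + 1L)
  kmers <- substring(bases, starts, starts + k - 1L)
  nw <- max(1L, length(kmers) - w + 1L)
  ww <- min(w, length(kmers))
  r <- rank(kmers, ties.method = "min")   # lexicographic order on A/C/G/T
  m <- vapply(seq_len(ww), function(j) r[seq_len(nw) + j - 1L], numeric(nw))
  if (nw == 1L) m <- matrix(m, nrow = 1L)
  off <- max.col(-m, ties.method = "first")
  pos <- seq_len(nw) + off - 1L
  keep <- !duplicated(pos)
  data.frame(minimizer = kmers[pos[keep]], pos = pos[keep],
             stringsAsFactors = FALSE)
}

#' Greedy strand-aware read clustering
#'
#' Reads are processed in order of decreasing mean quality; each read joins
#' the first existing cluster whose minimizer profile contains at least
#' `min_shared_fraction` of the read's minimizers, otherwise it founds a new
#' cluster. Minimizers are strand-specific, so reads in opposite
#' orientations never share a profile and form separate clusters; the
#' reverse-complement reconciliation happens later, at the consensus-merge
#' stage.
#'
#' With `refine = TRUE` a deterministic absorption pass follows: every read
#' is re-examined against the final profiles and moves to the largest
#' cluster whose profile clears the threshold (ties to the lower cluster
#' id). This collapses the small same-template fragments that greedy
#' founding inevitably produces at ~9% per-base error, without letting reads
#' cross between templates, whose profiles stay below the threshold.
#'
#' @param reads a [read_set()] of filtered reads.
#' @param cfg a [cluster_config()].
#' @return A list of class `read_clusters`: `assignments` (data frame
#'   `read_id`, `cluster_id`, `strand`) and `clusters` (data frame
#'   `cluster_id`, `size`, `fraction`, `representative`), clusters numbered
#'   1..K in decreasing size (founding order on ties). Cluster membership is
#'   a partition of the input reads.
#' @export
greedy_cluster <- function(reads, cfg = cluster_config()) {
  n <- nrow(reads)
  if (!n) stop("no reads to cluster")
  q <- mean_read_quality(reads)
  ord <- order(-q, seq_len(n))
  sketches <- lapply(reads$bases, function(b)
    unique(minimizer_sketch(b, cfg$kmer_size, cfg$window_size)$minimizer))

  profiles <- list()     # unique minimizers per cluster
  contrib <- integer(0)  # members that contributed to the profile
  member_of <- integer(n)
  for (i in ord) {
    sk <- sketches[[i]]
    placed <- FALSE
    if (length(sk)) {
      for (cl in seq_along(profiles)) {
        if (mean(sk %in% profiles[[cl]]) >= cfg$min_shared_fraction) {
          member_of[i] <- cl
          if (contrib[cl] < cfg$profile_max_reads) {
            profiles[[cl]] <- unique(c(profiles[[cl]], sk))
            contrib[cl] <- contrib[cl] + 1L
          }
          placed <- TRUE
          break
        }
      }
    }
    if (!placed) {
      profiles[[length(profiles) + 1L]] <- sk
      contrib <- c(contrib, 1L)
      member_of[i] <- length(profiles)
    }
  }

  if (isTRUE(cfg$refine) && length(profiles) > 1L) {
    sizes <- tabulate(member_of, length(profiles))
    new_member <- member_of
    for (i in seq_len(n)) {
      sk <- sketches[[i]]
      if (!length(sk)) next
      frac <- vapply(profiles, function(p) mean(sk %in% p), numeric(1))
      ok <- which(frac >= cfg$min_shared_fraction)
      if (length(ok)) {
        new_member[i] <- ok[order(-sizes[ok], ok)[1]]
      }
    }
    member_of <- new_member
  }

  # renumber clusters by decreasing size, founding order on ties
  sizes <- tabulate(member_of, length(profiles))
  keep <- which(sizes > 0L)
  keep <- keep[order(-sizes[keep], keep)]
  relabel <- integer(length(profiles))
  relabel[keep] <- seq_along(keep)
  cluster_id <- relabel[member_of]

  rep_id <- vapply(seq_along(keep), function(cl) {
    members <- which(cluster_id == cl)
    members[order(-q[members], members)][1]
  }, integer(1))

  assignments <- data.frame(read_id = reads$read_id,
                            cluster_id = cluster_id,
                            strand = "+",  # members share the representative's strand
                            stringsAsFactors = FALSE)
  clusters <- data.frame(cluster_id = seq_along(keep),
                         size = sizes[keep],
                         fraction = sizes[keep] / n,
                         representative = reads$read_id[rep_id],
                         stringsAsFactors = FALSE)
  structure(list(assignments = assignments, clusters = clusters,
                 n_reads = n), class = "read_clusters")
}

#' @export
print.read_clusters <- function(x, ...) {
  cat(sprintf("%d reads in %d cluster(s)\n", x$n_reads, nrow(x$clusters)))
  print(x$clusters)
  invisible(x)
}

#' Gate clusters by size fraction
#'
#' Retains clusters holding strictly more than `min_cluster_fraction` of the
#' clustered reads; a cluster at exactly the threshold is dropped. Small
#' clusters are where high-error and contaminant reads end up, which is the
#' point of the gate.
#'
#' @param clusters a `read_clusters` object or its `clusters` data frame.
#' @param total_reads denominator (defaults to the number of clustered
#'   reads).
#' @param min_cluster_fraction strict retention threshold.
#' @return The retained subset of the `clusters` data frame.
#' @export
gate_clusters <- function(clusters, total_reads = NULL,
                          min_cluster_fraction = 0.10) {
  df <- if (inherits(clusters, "read_clusters")) clusters$clusters else clusters
  if (is.null(total_reads)) {
    total_reads <- if (inherits(clusters, "read_clusters")) clusters$n_reads
                   else sum(df$size)
  }
  stopifnot(total_reads >= 1)
  keep <- df$size / total_reads > min_cluster_fraction
  if (!any(keep)) {
    stop("no cluster exceeds ", min_cluster_fraction * 100,
         "% of reads; lower min_cluster_fraction or inspect the input")
  }
  df[keep, , drop = FALSE]
}
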