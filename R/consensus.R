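#' Partial order alignment consensus
#'
#' Sequences are aligned progressively into a partial order graph: matched
#' positions reuse graph nodes, mismatches become alternative nodes aligned
#' to the same column, insertions add nodes, and every edge counts the
#' sequences traversing it. The consensus is the heaviest source-to-sink
#' path by traversal weight. Deterministic given the input order; callers
#' that want reproducible results across runs should therefore fix the
#' order (the pipeline inserts reads in decreasing quality order).
#'
#' @param seqs character vector of DNA sequences (>= 1).
#' @param match,mismatch,gap alignment scores used when threading each
#'   sequence into the graph.
#' @return The consensus DNA string.
#' @examples
#' poa_consensus(c("ACGT", "ACGT", "AGGT"))  # "ACGT"
#' @export
poa_consensus <- function(seqs, match = 2, mismatch = -4, gap = -6) {
  if (!length(seqs)) stop("poa_consensus needs at least one sequence")
  seqs <- seqs[nchar(seqs) > 0]
  if (!length(seqs)) stop("poa_consensus: all sequences are empty")
  cpp_poa_consensus(seqs, match, mismatch, gap)$consensus
}

#' Merge cluster consensuses across strand orientations
#'
#' Strand-aware clustering deliberately keeps forward and reverse reads
#' apart; this second round reunites them. Two cluster consensuses are
#' grouped when either the direct or the reverse-complement pairwise
#' identity reaches `identity_cutoff` (single linkage). Each non-anchor
#' cluster in a group records the orientation (`"as_is"` or `"rc"`) that
#' links it to the group's anchor (its largest cluster), so member reads can
#' later be oriented consistently for polishing.
#'
#' @param cons data frame with columns `cluster_id`, `consensus`, `n_reads`
#'   (and optionally `mean_quality`).
#' @param identity_cutoff grouping threshold on pairwise identity (see
#'   [pairwise_identity()]).
#' @return `cons` with added columns `group_id` (1..G, decreasing total
#'   reads), `orientation` relative to the group anchor, and `is_anchor`.
#' @export
merge_rc_consensus <- function(cons, identity_cutoff = 0.90) {
  stopifnot(nrow(cons) >= 1, identity_cutoff > 0.5, identity_cutoff <= 1)
  k <- nrow(cons)
  rc <- reverse_complement(cons$consensus)
  same <- matrix(FALSE, k, k)
  flip <- matrix(FALSE, k, k)
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        id_ff <- pairwise_identity(cons$consensus[i], cons$consensus[j])$identity
        id_fr <- pairwise_identity(cons$consensus[i], rc[j])$identity
        if (max(id_ff, id_fr) >= identity_cutoff) {
          same[i, j] <- same[j, i] <- TRUE
          flip[i, j] <- flip[j, i] <- id_fr > id_ff
        }
      }
    }
  }
  # connected components with orientation parity propagated from the anchor
  group <- rep(NA_integer_, k)
  orient <- rep("as_is", k)
  g <- 0L
  ord <- order(-cons$n_reads, cons$cluster_id)
  for (s in ord) {
    if (!is.na(group[s])) next
    g <- g + 1L
    group[s] <- g
    queue <- s
    while (length(queue)) {
      u <- queue[1]
      queue <- queue[-1]
      for (v in which(same[u, ] & is.na(group))) {
        group[v] <- g
        orient[v] <- if (xor(orient[u] == "rc", flip[u, v])) "rc" else "as_is"
        queue <- c(queue, v)
      }
    }
  }
  # renumber groups by total supporting reads
  tot <- tapply(cons$n_reads, group, sum)
  new_ids <- rank(-tot, ties.method = "first")
  cons$group_id <- as.integer(new_ids[as.character(group)])
  cons$orientation <- orient
  anchor <- tapply(seq_len(k), cons$group_id, function(ii)
    ii[order(-cons$n_reads[ii], cons$cluster_id[ii])][1])
  cons$is_anchor <- seq_len(k) %in% anchor
  cons[order(cons$group_id, -cons$n_reads, cons$cluster_id), , drop = FALSE]
}

#' Select the majority consensus group
#'
#' The group holding the most supporting reads wins; a tie goes to the group
#' with the higher mean read quality. The reported fraction is the share of
#' all reads that entered clustering, the quantity used downstream to decide
#' whether an identification needs investigation.
#'
#' @param merged output of [merge_rc_consensus()].
#' @param total_reads number of reads that entered clustering (the fraction
#'   denominator).
#' @param group_quality optional named vector of mean read quality per group
#'   for tie-breaking.
#' @return A list: `group_id`, `cluster_ids`, `n_reads`, `fraction`,
#'   `anchor_cluster`, `tie` (whether a tie was broken).
#' @export
select_majority <- function(merged, total_reads, group_quality = NULL) {
  stopifnot(total_reads >= 1)
  tot <- tapply(merged$n_reads, merged$group_id, sum)
  best_n <- max(tot)
  cand <- as.integer(names(tot)[tot == best_n])
  tie <- length(cand) > 1L
  if (tie && !is.null(group_quality)) {
    gq <- group_quality[as.character(cand)]
    cand <- cand[order(-gq, cand)]
  }
  gid <- cand[1]
  sel <- merged$group_id == gid
  list(group_id = gid,
       cluster_ids = merged$cluster_id[sel],
       n_reads = sum(merged$n_reads[sel]),
       fraction = sum(merged$n_reads[sel]) / total_reads,
       anchor_cluster = merged$cluster_id[sel & merged$is_anchor][1],
       tie = tie)
}

#' Polish a draft consensus by pileup majority voting
#'
#' Every read is aligned to the draft (free-end-gap global alignment); each
#' draft column takes the plurality vote over `{A,C,G,T,deletion}` among the
#' reads covering it (ties keep the draft base), and an insertion is placed
#' at a junction when more covering reads support the same inserted sequence
#' than support no insertion. Columns spanned by at most half of the reads are
#' dropped: free-end alignment makes read ends ragged (e.g. residual primer
#' bases on under-trimmed reads), and a plurality among a small covering
#' minority must not extend the consensus beyond the majority-supported
#' span. Rounds repeat until the consensus stops changing or `rounds` is
#' reached. Error-free reads leave the draft untouched, so polishing is a
#' fixed point on clean data.
#'
#' @param draft draft consensus DNA string.
#' @param reads character vector of read sequences, oriented like the draft.
#' @param rounds maximum number of polishing rounds.
#' @param match,mismatch,gap alignment scores for the read-to-draft
#'   alignments.
#' @return A list: `consensus`, `rounds_used`, `changed` (whether any round
#'   altered the draft), `n_reads`.
#' @export
polish_consensus <- function(draft, reads, rounds = 2,
                             match = 2, mismatch = -4, gap = -6) {
  stopifnot(nchar(draft) > 0)
  reads <- reads[nchar(reads) > 0]
  if (!length(reads)) {
    warning("no reads to polish with; returning draft unchanged")
    return(list(consensus = draft, rounds_used = 0L, changed = FALSE,
                n_reads = 0L))
  }
  changed_any <- FALSE
  used <- 0L
  for (r in seq_len(rounds)) {
    new <- .polish_round(draft, reads, match, mismatch, gap)
    used <- r
    if (identical(new, draft)) break
    draft <- new
    changed_any <- TRUE
  }
  # modal homopolymer run-length repair once column voting has converged,
  # then one more column pass in case the repair shifted an alignment
  if (rounds > 0) {
    for (k in 1:2) {
      rep <- .repair_run_lengths(draft, reads, match, mismatch, gap)
      if (identical(rep, draft)) break
      draft <- .polish_round(rep, reads, match, mismatch, gap)
      changed_any <- TRUE
    }
  }
  list(consensus = draft, rounds_used = used, changed = changed_any,
       n_reads = length(reads))
}
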