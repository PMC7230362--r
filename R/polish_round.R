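# Homopolymer run-length repair. The aligner places a run-length difference
# at an arbitrary (tie-broken) offset inside the run, so per-column votes
# about run indels scatter and a long run can stay one short of the truth:
# at nanopore-like rates a nine-base run sees a deletion in ~57% of reads,
# yet the single most common *observed run length* is still nine. Each read
# therefore casts one vote per run -- its net length change (insertions of
# the run's base at the run junctions minus deletions inside the run) -- and
# the run is re-emitted at the modal observed length, ties preferring the
# current draft length, then the closer, then the shorter length.
.repair_run_lengths <- function(draft, reads, match, mismatch, gap) {
  L <- nchar(draft)
  draft_ch <- strsplit(draft, "", fixed = TRUE)[[1]]
  rl <- rle(draft_ch)
  n_runs <- length(rl$lengths)
  if (!any(rl$lengths >= 2L)) return(draft)
  run_id <- rep(seq_len(n_runs), rl$lengths)
  run_len <- rep(rl$lengths, rl$lengths)
  in_run <- run_len >= 2L
  run_net <- vector("list", n_runs)
  n_cover <- integer(n_runs)

  for (rd in reads) {
    al <- cpp_overlap_align(rd, draft, match, mismatch, gap)
    a <- strsplit(al$a_gap, "", fixed = TRUE)[[1]]
    b <- strsplit(al$b_gap, "", fixed = TRUE)[[1]]
    dpos <- cumsum(b != "-")
    span <- which(a != "-")
    core <- seq(span[1], span[length(span)])
    is_d <- b[core] != "-"
    dcols <- core[is_d]
    if (!length(dcols)) next
    p <- dpos[dcols]
    covered <- unique(run_id[p[in_run[p]]])
    n_cover[covered] <- n_cover[covered] + 1L
    net <- integer(n_runs)
    del <- p[a[dcols] == "-"]
    del <- del[in_run[del]]
    if (length(del)) {
      tb <- table(run_id[del])
      ids <- as.integer(names(tb))
      net[ids] <- net[ids] - as.integer(tb)
    }
    icols <- core[!is_d]
    icols <- icols[a[icols] != "-"]
    if (length(icols)) {
      jpos <- dpos[icols]
      ok <- jpos >= p[1] & jpos < p[length(p)]
      for (k in which(ok)) {
        s <- a[icols[k]]
        j <- jpos[k]
        if (j < L && in_run[j + 1L] && draft_ch[j + 1L] == s) {
          net[run_id[j + 1L]] <- net[run_id[j + 1L]] + 1L
        } else if (in_run[j] && draft_ch[j] == s) {
          net[run_id[j]] <- net[run_id[j]] + 1L
        }
      }
    }
    for (r in which(net != 0L)) run_net[[r]] <- c(run_net[[r]], net[r])
  }

  out <- character(0)
  starts <- cumsum(rl$lengths) - rl$lengths + 1L
  for (r in seq_len(n_runs)) {
    R <- rl$lengths[r]
    if (R < 2L || n_cover[r] * 2L <= length(reads)) {
      out <- c(out, strrep(rl$values[r], R))
      next
    }
    nets <- run_net[[r]]
    lens <- c(rep(R, max(0L, n_cover[r] - length(nets))), pmax(0L, R + nets))
    tb <- table(lens)
    cand <- as.integer(names(tb)[tb == max(tb)])
    Lstar <- if (R %in% cand) R else cand[order(abs(cand - R), cand)][1]
    if (Lstar > 0L) out <- c(out, strrep(rl$values[r], Lstar))
  }
  paste(out, collapse = "")
}

# One round of pileup voting against a draft. Each draft column takes the
# plurality call over {A,C,G,T,deletion} among the reads covering it (ties
# keep the draft base); an insertion is accepted at a junction when more
# covering reads support the same inserted string than support no insertion.
# Columns spanned by at most half of the reads are dropped. The POA draft is
# deliberately biased long, so polishing mostly removes weakly supported
# bases -- the direction pileup voting handles best, since removals need only
# a per-column plurality while restorations would require insertion votes to
# agree on one junction.
.polish_round <- function(draft, reads, match, mismatch, gap) {
  L <- nchar(draft)
  syms <- c("A", "C", "G", "T", "-")
  votes <- matrix(0L, nrow = 5L, ncol = L)
  cov <- integer(L)
  jcov <- integer(max(L - 1L, 0L))        # junction after draft position p
  ins_votes <- vector("list", max(L - 1L, 0L))

  for (rd in reads) {
    al <- cpp_overlap_align(rd, draft, match, mismatch, gap)
    a <- strsplit(al$a_gap, "", fixed = TRUE)[[1]]
    b <- strsplit(al$b_gap, "", fixed = TRUE)[[1]]
    dpos <- cumsum(b != "-")
    span <- which(a != "-")
    lo <- span[1]; hi <- span[length(span)]
    core <- seq(lo, hi)
    is_d <- b[core] != "-"
    dcols <- core[is_d]
    if (!length(dcols)) next
    p <- dpos[dcols]
    sym <- match(a[dcols], syms)          # N or other ambiguity casts no vote
    okv <- !is.na(sym)
    if (any(okv)) {
      tb <- tabulate(sym[okv] + 5L * (p[okv] - 1L), nbins = 5L * L)
      votes <- votes + matrix(tb, nrow = 5L)
    }
    cov[p[1]:p[length(p)]] <- cov[p[1]:p[length(p)]] + 1L
    if (p[length(p)] > p[1]) {
      jcov[p[1]:(p[length(p)] - 1L)] <- jcov[p[1]:(p[length(p)] - 1L)] + 1L
    }
    icols <- core[!is_d]
    icols <- icols[a[icols] != "-"]
    if (length(icols)) {
      jpos <- dpos[icols]                 # draft position preceding the insertion
      ok <- jpos >= p[1] & jpos < p[length(p)]
      if (any(ok)) {
        ins <- split(a[icols][ok], jpos[ok])
        for (key in names(ins)) {
          j <- as.integer(key)
          ins_votes[[j]] <- c(ins_votes[[j]], paste(ins[[key]], collapse = ""))
        }
      }
    }
  }

  draft_ch <- strsplit(draft, "", fixed = TRUE)[[1]]
  n_reads <- length(reads)
  out <- character(0)
  for (pchr in seq_len(L)) {
    # a column must be spanned by a strict majority of reads to survive
    if (cov[pchr] * 2L > n_reads) {
      v <- votes[, pchr]
      top <- which(v == max(v))
      pick <- if (length(top) == 1L) top else {
        d <- match(draft_ch[pchr], syms)
        if (!is.na(d) && d %in% top) d else top[1]
      }
      if (pick != 5L) out <- c(out, syms[pick])
    }
    if (pchr < L && jcov[pchr] * 2L > n_reads && length(ins_votes[[pchr]])) {
      # plurality between "no insertion" and each candidate string
      tb <- table(ins_votes[[pchr]])
      best <- which.max(tb)
      if (tb[best] > jcov[pchr] - sum(tb)) out <- c(out, names(tb)[best])
    }
  }
  paste(out, collapse = "")
}
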