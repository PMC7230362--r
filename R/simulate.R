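#' Define an amplicon template
#'
#' The simulator's unit of truth: the full sequenced molecule is
#' `forward_index + forward_primer + insert + rc(reverse_primer) +
#' rc(reverse_index)`, where `rc()` is the reverse complement and primers and
#' indexes are written 5'->3' on their own strands (the convention used by
#' PCR protocols and by the demultiplexer).
#'
#' @param insert DNA string of the target barcode (default templates are
#'   421 bp; any non-empty length works).
#' @param forward_primer,reverse_primer primer sequences (`N`-free).
#' @param forward_index,reverse_index dual sample indexes (`N`-free).
#' @param name template name, used as the read-id prefix of simulated reads.
#' @param sample_label the sample the index pair encodes; defaults to `name`.
#' @return An object of class `amplicon_template`.
#' @export
amplicon_template <- function(insert, forward_primer, reverse_primer,
                              forward_index, reverse_index,
                              name = "template", sample_label = name) {
  insert <- toupper(insert)
  if (!nchar(insert)) stop("amplicon insert must be non-empty")
  refs <- reference_set(
    c("fwd_primer", "rev_primer", "fwd_index", "rev_index"),
    c(forward_primer, reverse_primer, forward_index, reverse_index),
    role = c("primer", "primer", "index", "index"))
  out <- list(
    insert = insert,
    forward_primer = refs$bases[1], reverse_primer = refs$bases[2],
    forward_index = refs$bases[3], reverse_index = refs$bases[4],
    name = name, sample_label = sample_label)
  out$full <- paste0(out$forward_index, out$forward_primer, out$insert,
                     reverse_complement(out$reverse_primer),
                     reverse_complement(out$reverse_index))
  class(out) <- "amplicon_template"
  out
}

#' Define a nanopore-like read error model
#'
#' Errors are drawn per template position, independently and in template
#' order: a position is deleted with probability `del_rate` (multiplied by
#' `homopolymer_del_multiplier` inside homopolymer runs of length >=
#' `hp_min_len`), else substituted with probability `sub_rate`; after each
#' position a uniform random base is inserted with probability `ins_rate`.
#' Deletion and substitution are mutually exclusive at a position, so
#' realised per-class counts are binomial at exactly the configured rates.
#' Per-base qualities are constant within a read, at a read-level mean drawn
#' from `Normal(mean_read_quality, quality_sd)` clamped to `[2, 40]` -- real
#' basecallers report richer per-base structure, but per-read means are what
#' the downstream quality filter consumes.
#'
#' @param sub_rate,ins_rate,del_rate per-base error probabilities in `[0,1)`.
#' @param homopolymer_del_multiplier factor applied to `del_rate` inside
#'   homopolymer runs; nanopore indel errors concentrate there.
#' @param hp_min_len minimum run length treated as a homopolymer.
#' @param mean_read_quality,quality_sd Phred mean and spread of read-level
#'   quality. A mean of 10.5 corresponds to ~9% expected base error, matching
#'   the default 3%/3%/3% error split.
#' @return An object of class `error_model`.
#' @export
error_model <- function(sub_rate = 0.03, ins_rate = 0.03, del_rate = 0.03,
                        homopolymer_del_multiplier = 3, hp_min_len = 3,
                        mean_read_quality = 10.5, quality_sd = 1.5) {
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0 | rates >= 1)) stop("error rates must lie in [0, 1)")
  if (homopolymer_del_multiplier < 1) stop("homopolymer multiplier must be >= 1")
  eff <- del_rate * homopolymer_del_multiplier
  if (eff + sub_rate >= 1) stop("effective deletion + substitution rate must stay below 1")
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate, del_rate = del_rate,
                 homopolymer_del_multiplier = homopolymer_del_multiplier,
                 hp_min_len = hp_min_len,
                 mean_read_quality = mean_read_quality,
                 quality_sd = quality_sd),
            class = "error_model")
}

#' Flag positions inside homopolymer runs
#'
#' @param bases a single DNA string.
#' @param min_len minimum run length that counts as a homopolymer.
#' @return Logical vector, one element per base.
#' @export
homopolymer_mask <- function(bases, min_len = 3) {
  ch <- strsplit(bases, "", fixed = TRUE)[[1]]
  r <- rle(ch)
  rep(r$lengths >= min_len, r$lengths)
}

#' Simulate nanopore-like amplicon reads with known truth
#'
#' Each read is the full template (or its reverse complement, with
#' probability `1 - strand_fraction`) corrupted by the error model. The same
#' seed yields byte-identical output.
#'
#' @param template an [amplicon_template()].
#' @param n number of reads (>= 1).
#' @param model an [error_model()].
#' @param strand_fraction probability that a read is forward-stranded.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param chimera_rate probability that a read is a two-template concatenation
#'   (an artefact class the length filter is meant to remove); default 0.
#' @return A list with elements `reads` (a [read_set()]) and `truth` (a data
#'   frame with one row per read: `read_id`, `template`, `sample_label`,
#'   `strand`, `chimera`, applied error counts `n_sub`/`n_ins`/`n_del`, and
#'   the drawn `read_quality`).
#' @examples
#' tpl <- amplicon_template(toy_inserts()$bases[1],
#'                          toy_primers()$bases[1], toy_primers()$bases[2],
#'                          toy_index_panel(1)$forward_index,
#'                          toy_index_panel(1)$reverse_index,
#'                          name = "spA", sample_label = "sample1")
#' sim <- simulate_reads(tpl, 5, seed = 1)
#' sim$truth$n_sub
#' @export
simulate_reads <- function(template, n, model = error_model(),
                           strand_fraction = 0.5, seed = NULL,
                           chimera_rate = 0) {
  stopifnot(inherits(template, "amplicon_template"),
            inherits(model, "error_model"), n >= 1)
  if (!is.null(seed)) withr::local_seed(as.integer(seed))

  fwd <- template$full
  rev <- reverse_complement(fwd)
  fwd_ch <- strsplit(fwd, "", fixed = TRUE)[[1]]
  rev_ch <- strsplit(rev, "", fixed = TRUE)[[1]]
  fwd_hp <- homopolymer_mask(fwd, model$hp_min_len)
  rev_hp <- rev(fwd_hp)  # complementing preserves run structure

  bases_out <- character(n)
  quals_out <- character(n)
  strand <- character(n)
  n_sub <- n_ins <- n_del <- integer(n)
  chim <- logical(n)
  other <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))

  for (i in seq_len(n)) {
    is_fwd <- runif(1) < strand_fraction
    ch <- if (is_fwd) fwd_ch else rev_ch
    hp <- if (is_fwd) fwd_hp else rev_hp
    chim[i] <- chimera_rate > 0 && runif(1) < chimera_rate
    if (chim[i]) {
      ch <- c(ch, ch)
      hp <- c(hp, hp)
    }
    L <- length(ch)
    del_thr <- model$del_rate * ifelse(hp, model$homopolymer_del_multiplier, 1)
    u <- runif(L)
    del <- u < del_thr
    sub <- !del & u < del_thr + model$sub_rate
    ins <- runif(L) < model$ins_rate
    piece <- ch
    if (any(sub)) {
      piece[sub] <- vapply(ch[sub],
                           function(b) sample(other[[b]], 1), character(1))
    }
    piece[del] <- ""
    if (any(ins)) {
      piece[ins] <- paste0(piece[ins],
                           sample(c("A", "C", "G", "T"), sum(ins), TRUE))
    }
    bases_out[i] <- paste(piece, collapse = "")
    q <- round(min(40, max(2, rnorm(1, model$mean_read_quality, model$quality_sd))))
    quals_out[i] <- strrep(intToUtf8(q + 33L), nchar(bases_out[i]))
    strand[i] <- if (is_fwd) "forward" else "reverse"
    n_sub[i] <- sum(sub)
    n_ins[i] <- sum(ins)
    n_del[i] <- sum(del)
  }

  ids <- sprintf("%s_%05d", template$name, seq_len(n))
  reads <- read_set(ids, bases_out, quals_out)
  truth <- data.frame(
    read_id = ids, template = template$name,
    sample_label = template$sample_label, strand = strand, chimera = chim,
    n_sub = n_sub, n_ins = n_ins, n_del = n_del,
    read_quality = vapply(quals_out, function(s) utf8ToInt(substr(s, 1, 1)),
                          integer(1), USE.NAMES = FALSE) - 33L,
    stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

#' Mix contaminant reads into a sample at a fixed fraction
#'
#' Emulates within-sample contamination arising during library preparation:
#' both read sets carry the same index pair and therefore demultiplex to the
#' same sample. The output has as many reads as `primary`, of which exactly
#' `round(fraction * n)` are drawn from `contaminant`; order is shuffled
#' deterministically under `seed` and truth labels are preserved.
#'
#' @param primary,contaminant lists as returned by [simulate_reads()], with
#'   identical `sample_label`s.
#' @param fraction contaminant fraction in `[0, 1)`.
#' @param seed integer seed for the draw and the shuffle.
#' @return A list with `reads` and `truth`, same shape as [simulate_reads()].
#' @export
mix_contamination <- function(primary, contaminant, fraction, seed = NULL) {
  if (fraction < 0 || fraction >= 1) stop("fraction must lie in [0, 1)")
  if (!identical(unique(primary$truth$sample_label),
                 unique(contaminant$truth$sample_label))) {
    stop("primary and contaminant reads must carry the same index pair ",
         "(identical sample_label)")
  }
  n <- nrow(primary$reads)
  nc <- round(fraction * n)
  if (nc > nrow(contaminant$reads)) {
    stop("contaminant set too small: need ", nc, " reads")
  }
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  keep_p <- sort(sample(n, n - nc))
  keep_c <- sort(sample(nrow(contaminant$reads), nc))
  reads <- rbind(primary$reads[keep_p, ], contaminant$reads[keep_c, ])
  truth <- rbind(primary$truth[keep_p, ], contaminant$truth[keep_c, ])
  ord <- sample(nrow(reads))
  reads <- reads[ord, ]
  truth <- truth[ord, ]
  rownames(reads) <- rownames(truth) <- NULL
  class(reads) <- c("read_set", "data.frame")
  list(reads = reads, truth = truth)
}
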