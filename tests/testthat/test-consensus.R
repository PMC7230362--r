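# independent oracle: per-column plurality on gap-free equal-length inputs,
# ties resolved to the base seen first among the tied candidates in input order
column_majority <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  paste(apply(m, 2, function(col) {
    tab <- table(factor(col, levels = unique(col)))
    names(tab)[which.max(tab)]
  }), collapse = "")
}

test_that("POA consensus of identical sequences is the sequence", {
  expect_identical(poa_consensus(c("ACGTACGT", "ACGTACGT", "ACGTACGT")),
                   "ACGTACGT")
  expect_identical(poa_consensus("TTGACA"), "TTGACA")
  expect_identical(poa_consensus(c("ACGT", "ACGT", "AGGT")), "ACGT")
  expect_error(poa_consensus(character(0)), "at least one")
})

test_that("POA equals column majority on gap-free equal-length inputs", {
  # substitution-only corruption keeps all inputs equal length and gap-free;
  # clear per-column majorities make the heaviest path the majority path
  set.seed(42)
  for (case in 1:200) {
    tplt <- random_dna(sample(25:60, 1))
    n <- sample(c(5, 7, 9), 1)
    seqs <- vapply(seq_len(n), function(i) {
      k <- rbinom(1, nchar(tplt), 0.03)
      if (k) mutate_subs(tplt, sample(nchar(tplt), k)) else tplt
    }, character(1))
    expect_identical(poa_consensus(seqs), column_majority(seqs))
  }
})

test_that("the polished consensus commutes with reverse complement", {
  # the draft stage breaks exact strand symmetry (deliberately long-biased,
  # with tie-broken indel placements), but the polished consensus -- the
  # pipeline's actual consensus operator -- is strand-symmetric
  tpl <- fix_template()
  sim <- simulate_reads(tpl, 30, strand_fraction = 1, seed = 301)
  fwd <- poa_consensus(sim$reads$bases)
  pol_f <- polish_consensus(fwd, sim$reads$bases)$consensus
  rc_reads <- reverse_complement(sim$reads$bases)
  pol_r <- polish_consensus(poa_consensus(rc_reads), rc_reads)$consensus
  expect_identical(reverse_complement(pol_r), pol_f)
})

test_that("100 noisy reads polish to within edit distance 3 of the truth", {
  tpl <- fix_template()
  sim <- simulate_reads(tpl, 100, strand_fraction = 1, seed = 302)
  draft <- poa_consensus(sim$reads$bases)
  # the draft errs long by design; identity stays high before polishing
  expect_lte(as.integer(adist(draft, tpl$full)), 60)
  pol <- polish_consensus(draft, sim$reads$bases)
  expect_lte(as.integer(adist(pol$consensus, tpl$full)), 3)
})

test_that("consensus merging joins reverse complements and respects the cutoff", {
  set.seed(7)
  a <- random_dna(421)
  cons <- data.frame(cluster_id = 1:2,
                     consensus = c(a, reverse_complement(a)),
                     n_reads = c(30L, 20L))
  merged <- merge_rc_consensus(cons, 0.9)
  expect_identical(unique(merged$group_id), 1L)
  expect_identical(merged$orientation[merged$cluster_id == 2], "rc")
  expect_true(merged$is_anchor[merged$cluster_id == 1])

  # 42 scattered substitutions in 421 -> identity 379/421 = 0.9002: merges
  # (scattered, so isolated mismatch columns stay in the alignment)
  close <- data.frame(cluster_id = 1:2,
                      consensus = c(a, mutate_subs(a, round(seq(8, 414,
                                                               length.out = 42)))),
                      n_reads = c(30L, 20L))
  expect_identical(unique(merge_rc_consensus(close, 0.9)$group_id), 1L)
  # 46 scattered substitutions -> identity 375/421 = 0.8907: stays split
  apart <- data.frame(cluster_id = 1:2,
                      consensus = c(a, mutate_subs(a, round(seq(8, 414,
                                                               length.out = 46)))),
                      n_reads = c(30L, 20L))
  expect_identical(sort(unique(merge_rc_consensus(apart, 0.9)$group_id)), 1:2)
  # the bundled inserts (~71% identity) never merge
  far <- data.frame(cluster_id = 1:2, consensus = fix_inserts$bases,
                    n_reads = c(30L, 20L))
  expect_identical(sort(unique(merge_rc_consensus(far, 0.9)$group_id)), 1:2)
})

test_that("majority selection counts reads and breaks ties by quality", {
  merged <- data.frame(cluster_id = 1:3, consensus = "ACGT",
                       n_reads = c(60L, 25L, 15L), group_id = c(1L, 1L, 2L),
                       orientation = "as_is",
                       is_anchor = c(TRUE, FALSE, TRUE))
  maj <- select_majority(merged, total_reads = 100)
  expect_identical(maj$group_id, 1L)
  expect_equal(maj$fraction, 0.85)
  expect_identical(maj$anchor_cluster, 1L)

  tie <- data.frame(cluster_id = 1:2, consensus = "ACGT",
                    n_reads = c(50L, 50L), group_id = 1:2,
                    orientation = "as_is", is_anchor = TRUE)
  maj2 <- select_majority(tie, 100, group_quality = c("1" = 10, "2" = 14))
  expect_true(maj2$tie)
  expect_identical(maj2$group_id, 2L)
})

test_that("polishing is a fixed point on error-free reads", {
  set.seed(9)
  draft <- random_dna(300)
  pol <- polish_consensus(draft, rep(draft, 20))
  expect_identical(pol$consensus, draft)
  expect_false(pol$changed)
})

test_that("polishing restores a deleted base and respects majority deletions", {
  set.seed(10)
  truth <- paste0(random_dna(150), "T", random_dna(150))
  draft <- paste0(substr(truth, 1, 150), substr(truth, 152, 301))
  pol <- polish_consensus(draft, rep(truth, 50))
  expect_identical(pol$consensus, truth)

  # homopolymer run truncated in the draft: clean reads restore it
  truth_hp <- paste0(random_dna(100), strrep("A", 6), random_dna(100))
  draft_hp <- paste0(substr(truth_hp, 1, 100), strrep("A", 5),
                     substr(truth_hp, 107, 206))
  pol2 <- polish_consensus(draft_hp, rep(truth_hp, 50))
  expect_identical(pol2$consensus, truth_hp)
  # ... but when 60% of reads carry the deletion, majority rules: not restored
  reads <- c(rep(truth_hp, 20), rep(draft_hp, 30))
  pol3 <- polish_consensus(draft_hp, reads)
  expect_identical(pol3$consensus, draft_hp)
})

test_that("polishing with no usable reads warns and returns the draft", {
  expect_warning(pol <- polish_consensus("ACGTACGT", character(0)),
                 "no reads")
  expect_identical(pol$consensus, "ACGTACGT")
})

test_that("polishing corrects a noisy POA draft towards the template", {
  tpl <- fix_template()
  sim <- simulate_reads(tpl, 40, strand_fraction = 1, seed = 303)
  draft <- poa_consensus(sim$reads$bases[1:10])   # deliberately coarse draft
  pol <- polish_consensus(draft, sim$reads$bases, rounds = 2)
  d_before <- as.integer(adist(draft, tpl$full))
  d_after <- as.integer(adist(pol$consensus, tpl$full))
  expect_lte(d_after, d_before)
  expect_lte(d_after, 2)
})
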