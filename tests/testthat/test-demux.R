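# Reads constructed directly from templates (error-free unless noted), so
# every expectation below is threshold arithmetic on known edit distances.

clean_read <- function(pair = 1, insert = fix_inserts$bases[1], rc = FALSE,
                       id = "r1") {
  tpl <- fix_template(insert = insert, pair = pair)
  b <- if (rc) reverse_complement(tpl$full) else tpl$full
  fix_reads(b, ids = id)
}

test_that("locate_index agrees with a brute-force sliding-window oracle", {
  set.seed(8)
  idx <- fix_panel$forward_index[1]
  for (rep in 1:10) {
    prefix <- random_dna(sample(0:20, 1))
    planted <- if (rep <= 5) idx else mutate_subs(idx, sample(24, rep - 5))
    text <- paste0(prefix, planted, random_dna(40))
    # oracle: edit distance of the index against every substring
    L <- nchar(text)
    best <- Inf
    for (s in 1:L) for (e in s:min(L, s + 40)) {
      best <- min(best, adist(idx, substr(text, s, e)))
    }
    hit <- locate_index(text, idx, search_window = min(150, L))
    expect_identical(hit$edits, as.integer(best))
  }
})

test_that("an index planted at the read start is found exactly", {
  idx <- fix_panel$forward_index[1]
  hit <- locate_index(paste0(idx, random_dna(60)), idx, 100)
  expect_identical(hit$edits, 0L)
  expect_identical(hit$start, 0L)
  expect_identical(hit$end, 24L)
})

test_that("random reads do not contain a 24-nt index within 2 edits", {
  set.seed(12)
  idx <- fix_panel$forward_index[1]
  hits <- vapply(1:50, function(i)
    locate_index(random_dna(150), idx, 150)$edits, integer(1))
  expect_true(all(hits > 2))
})

test_that("score mode: exact dual indexes score 100, one edit scores 95.83", {
  r <- clean_read()
  dm <- demux_reads(r, fix_panel, mode = "score")
  expect_identical(dm$assignments$sample_label, fix_panel$sample_label[1])
  expect_equal(dm$assignments$score, 100)

  # one substitution inside the forward index: 100*23/24 < 99 -> unassigned
  tpl <- fix_template()
  b <- paste0(mutate_subs(substr(tpl$full, 1, 24), 5),
              substr(tpl$full, 25, nchar(tpl$full)))
  dm1 <- demux_reads(fix_reads(b), fix_panel, mode = "score")
  expect_true(is.na(dm1$assignments$sample_label))
  # the same read passes at a laxer min_score
  dm2 <- demux_reads(fix_reads(b), fix_panel, mode = "score", min_score = 95)
  expect_identical(dm2$assignments$sample_label, fix_panel$sample_label[1])
  expect_equal(dm2$assignments$score, 100 * 23 / 24, tolerance = 1e-9)
})

test_that("score mode trims indexes but retains primers", {
  tpl <- fix_template()
  dm <- demux_reads(clean_read(), fix_panel, mode = "score")
  trimmed <- dm$samples[[fix_panel$sample_label[1]]]$bases
  expect_identical(trimmed, paste0(tpl$forward_primer, tpl$insert,
                                   reverse_complement(tpl$reverse_primer)))
})

test_that("edit mode honours the 2-edit index threshold", {
  tpl <- fix_template()
  # substitutions planted at interior index positions, so the semi-global
  # edit distance equals the planted count exactly
  plant <- function(n_f, n_r) {
    full <- tpl$full
    fwd <- mutate_subs(substr(full, 1, 24), c(5, 10, 15)[seq_len(n_f)])
    rev <- mutate_subs(substr(full, nchar(full) - 23, nchar(full)),
                       c(5, 10, 15)[seq_len(n_r)])
    fix_reads(paste0(fwd, substr(full, 25, nchar(full) - 24), rev))
  }
  ok <- demux_reads(plant(2, 2), fix_panel, "edit", fix_primers)
  expect_identical(ok$assignments$sample_label, fix_panel$sample_label[1])
  expect_identical(ok$assignments$edits_fwd, 2L)
  bad <- demux_reads(plant(3, 0), fix_panel, "edit", fix_primers)
  expect_true(is.na(bad$assignments$sample_label))
})

test_that("edit mode trims through primers, retaining an unlocatable primer", {
  tpl <- fix_template()
  dm <- demux_reads(clean_read(), fix_panel, "edit", fix_primers)
  expect_identical(dm$samples[[fix_panel$sample_label[1]]]$bases, tpl$insert)

  # corrupt the forward primer to exactly 12 edits: index-only trim there
  full <- tpl$full
  primer12 <- mutate_subs(substr(full, 25, 49), seq(2, 24, by = 2))
  broken <- paste0(substr(full, 1, 24), primer12,
                   substr(full, 50, nchar(full)))
  dm2 <- demux_reads(fix_reads(broken), fix_panel, "edit", fix_primers)
  got <- dm2$samples[[fix_panel$sample_label[1]]]$bases
  expect_identical(substr(got, nchar(got) - 420, nchar(got)), tpl$insert)
  expect_gt(nchar(got), 421)  # the corrupted primer region is retained
})

test_that("assigned reads form a partition with zero cross-sample errors", {
  tplA <- fix_template(pair = 1)
  tplB <- fix_template(insert = fix_inserts$bases[2], pair = 2, name = "spB")
  simA <- simulate_reads(tplA, 60, seed = 51)
  simB <- simulate_reads(tplB, 60, seed = 52)
  reads <- rbind(simA$reads, simB$reads)
  class(reads) <- c("read_set", "data.frame")
  dm <- demux_reads(reads, fix_panel, "edit", fix_primers)
  all_ids <- unlist(lapply(dm$samples, function(s) s$read_id))
  expect_false(any(duplicated(all_ids)))         # at most one sample per read
  assigned <- dm$assignments[!is.na(dm$assignments$sample_label), ]
  truth <- rbind(simA$truth, simB$truth)
  m <- merge(assigned, truth[, c("read_id", "sample_label")], by = "read_id")
  expect_true(all(m$sample_label.x == m$sample_label.y))  # no cross-assignment
})

test_that("zero-error reads demultiplex with 100% accuracy in both modes", {
  zero <- error_model(0, 0, 0, quality_sd = 0)
  reads <- rbind(simulate_reads(fix_template(pair = 1), 30, model = zero,
                                seed = 61)$reads,
                 simulate_reads(fix_template(insert = fix_inserts$bases[2],
                                             pair = 2, name = "spB"),
                                30, model = zero, seed = 62)$reads)
  class(reads) <- c("read_set", "data.frame")
  for (mode in c("score", "edit")) {
    dm <- demux_reads(reads, fix_panel, mode, fix_primers)
    expect_identical(sum(!is.na(dm$assignments$sample_label)), 60L)
    expect_identical(nrow(dm$samples[[fix_panel$sample_label[1]]]), 30L)
    expect_identical(nrow(dm$samples[[fix_panel$sample_label[2]]]), 30L)
  }
})

test_that("a read and its reverse complement demultiplex identically", {
  sim <- simulate_reads(fix_template(), 20, seed = 71)
  fwd <- demux_reads(sim$reads, fix_panel, "edit", fix_primers)
  rc_reads <- sim$reads
  rc_reads$bases <- reverse_complement(rc_reads$bases)
  rc_reads$quals <- vapply(rc_reads$quals,
                           function(s) intToUtf8(rev(utf8ToInt(s))),
                           character(1))
  rc <- demux_reads(rc_reads, fix_panel, "edit", fix_primers)
  expect_identical(fwd$assignments$sample_label, rc$assignments$sample_label)
  s <- fix_panel$sample_label[1]
  expect_identical(fwd$samples[[s]]$bases, rc$samples[[s]]$bases)
})

test_that("a read matching two pairs equally well is left unassigned", {
  # hybrid read: forward index of pair 1, reverse index of pair 2 --
  # each pair matches exactly one of its two indexes
  tpl1 <- fix_template(pair = 1)
  hyb <- paste0(fix_panel$forward_index[1], substr(tpl1$full, 25, 470),
                reverse_complement(fix_panel$reverse_index[2]))
  dm <- demux_reads(fix_reads(hyb), fix_panel, "edit", fix_primers)
  expect_true(is.na(dm$assignments$sample_label))
})

test_that("demux_summary tabulates reads per sample", {
  sim <- simulate_reads(fix_template(), 40, seed = 81)
  dm <- demux_reads(sim$reads, fix_panel, "edit", fix_primers)
  tab <- demux_summary(dm$assignments)
  expect_identical(sum(tab$n_reads), 40L)
  expect_true(fix_panel$sample_label[1] %in% tab$sample_label)
})
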