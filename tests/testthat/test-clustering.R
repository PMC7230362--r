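test_that("minimizer sketches are deterministic and error-tolerant", {
  set.seed(4)
  s <- random_dna(421)
  sk1 <- minimizer_sketch(s, 13, 5)
  sk2 <- minimizer_sketch(s, 13, 5)
  expect_identical(sk1, sk2)
  expect_true(all(substring(s, sk1$pos, sk1$pos + 12) == sk1$minimizer))
  # one substitution leaves > 80% of minimizers shared
  s2 <- mutate_subs(s, 200)
  sk3 <- minimizer_sketch(s2, 13, 5)
  shared <- mean(sk1$minimizer %in% sk3$minimizer)
  expect_gt(shared, 0.8)
  # shorter than k: empty sketch
  expect_identical(nrow(minimizer_sketch("ACGT", 13, 5)), 0L)
})

test_that("clean reads from one template in both strands give two strand clusters", {
  tpl <- fix_template()
  sim <- simulate_reads(tpl, 60, seed = 201)   # unoriented reads, ~50/50 strands
  cl <- greedy_cluster(sim$reads, cluster_config())
  expect_identical(nrow(cl$clusters), 2L)
  # each cluster is strand-pure and the two clusters cover everything
  m <- merge(cl$assignments, sim$truth[, c("read_id", "strand")])
  tab <- table(m$cluster_id, m$strand)
  expect_true(all(rowSums(tab > 0) == 1))
  expect_identical(sum(cl$clusters$size), 60L)
})

test_that("same-strand clean reads form a single cluster", {
  sim <- simulate_reads(fix_template(), 40, strand_fraction = 1, seed = 202)
  cl <- greedy_cluster(sim$reads, cluster_config())
  expect_identical(nrow(cl$clusters), 1L)
  expect_equal(cl$clusters$fraction, 1)
})

test_that("templates at <=80% identity never share a cluster (vs brute force)", {
  # clustering operates on demultiplexed, primer-trimmed reads (insert
  # only): raw reads from two templates under one index pair share their
  # entire flank sequence, which is exactly what trimming removes
  simA <- simulate_reads(fix_template(), 60, strand_fraction = 1, seed = 203)
  simB <- simulate_reads(fix_template_b(), 60, strand_fraction = 1, seed = 204)
  raw <- rbind(simA$reads, simB$reads)
  class(raw) <- c("read_set", "data.frame")
  dm <- demux_reads(raw, fix_panel, "edit", fix_primers)
  reads <- dm$samples[[fix_panel$sample_label[1]]]
  expect_gte(nrow(reads), 25)
  cl <- greedy_cluster(reads, cluster_config())
  m <- merge(cl$assignments,
             rbind(simA$truth, simB$truth)[, c("read_id", "template")])
  tab <- table(m$cluster_id, m$template)
  expect_true(all(rowSums(tab > 0) == 1))   # no mixed cluster

  # brute-force oracle: single-linkage on pairwise identity >= 0.78
  # (same-template read pairs at ~9% error sit above 0.80, cross-template
  # pairs below 0.71)
  n <- nrow(reads)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    adj[i, j] <- adj[j, i] <-
      pairwise_identity(reads$bases[i], reads$bases[j])$identity >= 0.78
  }
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cid <- cid + 1L
    q <- s
    while (length(q)) {
      u <- q[1]; q <- q[-1]
      if (comp[u]) next
      comp[u] <- cid
      q <- c(q, which(adj[u, ] & comp == 0L))
    }
  }
  # the oracle partition and the minimizer partition agree
  expect_identical(length(unique(comp)), 2L)
  split_oracle <- split(reads$read_id, comp)
  split_mini <- split(cl$assignments$read_id, cl$assignments$cluster_id)
  expect_true(all(vapply(split_mini, function(g)
    any(vapply(split_oracle, function(o) all(g %in% o), logical(1))),
    logical(1))))
})

test_that("reverse-complementing all reads preserves the cluster structure", {
  sim <- simulate_reads(fix_template(), 50, seed = 205)
  cl1 <- greedy_cluster(sim$reads, cluster_config())
  rc <- sim$reads
  rc$bases <- reverse_complement(rc$bases)
  rc$quals <- vapply(rc$quals, function(s) intToUtf8(rev(utf8ToInt(s))),
                     character(1))
  cl2 <- greedy_cluster(rc, cluster_config())
  p1 <- split(cl1$assignments$read_id, cl1$assignments$cluster_id)
  p2 <- split(cl2$assignments$read_id, cl2$assignments$cluster_id)
  expect_identical(lapply(p1, sort), lapply(p2, sort))
})

test_that("cluster membership is a partition", {
  sim <- simulate_reads(fix_template(), 80, seed = 206)
  cl <- greedy_cluster(sim$reads, cluster_config())
  expect_setequal(cl$assignments$read_id, sim$reads$read_id)
  expect_false(any(duplicated(cl$assignments$read_id)))
  expect_identical(sum(cl$clusters$size), 80L)
})

test_that("the >10% gate is strict and errors when nothing survives", {
  df <- data.frame(cluster_id = 1:3, size = c(850L, 100L, 50L),
                   fraction = c(0.85, 0.10, 0.05), representative = "x")
  kept <- gate_clusters(df, total_reads = 1000)
  expect_identical(kept$cluster_id, 1L)   # exactly 10% is excluded
  all3 <- gate_clusters(data.frame(cluster_id = 1:3,
                                   size = c(400L, 350L, 250L),
                                   fraction = c(.4, .35, .25),
                                   representative = "x"),
                        total_reads = 1000)
  expect_identical(nrow(all3), 3L)
  one <- gate_clusters(data.frame(cluster_id = 1L, size = 10L, fraction = 1,
                                  representative = "x"), total_reads = 10)
  expect_identical(nrow(one), 1L)
  expect_error(gate_clusters(data.frame(cluster_id = 1:2, size = c(5L, 5L),
                                        fraction = c(.05, .05),
                                        representative = "x"),
                             total_reads = 100),
               "lower")
})

test_that("the representative is the highest-quality member", {
  set.seed(1)
  bases <- replicate(5, random_dna(400))
  q <- c(10, 30, 12, 11, 9)
  reads <- read_set(sprintf("r%d", 1:5),
                    c(bases[1], bases[1], bases[1], bases[1], bases[1]),
                    vapply(q, function(qq) strrep(intToUtf8(qq + 33L), 400),
                           character(1)))
  cl <- greedy_cluster(reads, cluster_config())
  expect_identical(cl$clusters$representative, "r2")
})
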