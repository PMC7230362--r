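#' Pipeline configuration
#'
#' One object holding every tunable of the pipeline, with defaults matching
#' the standard stringent amplicon-barcoding setup: score-mode threshold 99,
#' edit-mode tolerances of 2 index / 11 primer differences, mean quality of
#' at least 7, length window 321-521 bp, benchmark subsets of 100/500/5000
#' reads,
#' a strict >10% cluster gate, and a 0.9 consensus-merge identity cutoff.
#' The default demultiplexing mode for full pipeline runs is `"edit"`, the
#' general-purpose mode for user-supplied index panels.
#'
#' @param demux_mode `"edit"` or `"score"`.
#' @param min_score score-mode threshold (percent).
#' @param max_index_edits,max_primer_edits edit-mode tolerances.
#' @param search_window bases searched for indexes at each read end.
#' @param min_mean_q,min_len,max_len read filter (see [filter_config()]).
#' @param subset_size optional per-sample subset before clustering (`NULL` =
#'   use all filtered reads).
#' @param subset_sizes benchmark grid of subset sizes.
#' @param kmer_size,window_size,min_shared_fraction,min_cluster_fraction,profile_max_reads,refine
#'   clustering parameters (see [cluster_config()]).
#' @param merge_identity consensus-merge identity cutoff.
#' @param polish_rounds pileup polishing rounds.
#' @param poa_max_reads at most this many (highest-quality) reads build each
#'   cluster's POA graph; polishing still uses every supporting read.
#' @param match,mismatch,gap alignment scores shared by POA, merging and
#'   polishing.
#' @param expected_length,length_tol,min_identity,min_fraction reporting
#'   criteria (see [evaluate_criteria()]).
#' @param seed base seed for all randomised steps (subsetting).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(demux_mode = "edit", min_score = 99,
                            max_index_edits = 2, max_primer_edits = 11,
                            search_window = 150,
                            min_mean_q = 7, min_len = 321, max_len = 521,
                            subset_size = NULL,
                            subset_sizes = c(100, 500, 5000),
                            kmer_size = 13, window_size = 5,
                            min_shared_fraction = 0.07,
                            min_cluster_fraction = 0.10,
                            profile_max_reads = 100, refine = TRUE,
                            merge_identity = 0.90, polish_rounds = 2,
                            poa_max_reads = 500,
                            match = 2, mismatch = -4, gap = -6,
                            expected_length = 421, length_tol = 5,
                            min_identity = 99, min_fraction = 0.75,
                            seed = 1) {
  cfg <- as.list(environment())
  cfg$demux_mode <- match.arg(cfg$demux_mode, c("edit", "score"))
  filter_config(min_mean_q, min_len, max_len)       # validate
  cluster_config(kmer_size, window_size, min_shared_fraction,
                 min_cluster_fraction, profile_max_reads, refine)
  stopifnot(merge_identity > 0.5, merge_identity <= 1, polish_rounds >= 0)
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration file
#'
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   [pipeline_config()] (unknown fields are rejected).
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

# downstream analysis of one sample's filtered reads:
# subset -> cluster -> gate -> POA -> merge -> majority -> polish -> trim -> id
.analyze_filtered <- function(filtered, primers, references, config,
                              subset_size, subset_seed, sample_label) {
  if (!nrow(filtered)) stop("no reads passed filtering")
  used <- filtered
  if (!is.null(subset_size)) {
    used <- suppressWarnings(subset_reads(filtered, subset_size, subset_seed))
  }
  ccfg <- cluster_config(config$kmer_size, config$window_size,
                         config$min_shared_fraction,
                         config$min_cluster_fraction,
                         config$profile_max_reads, config$refine)
  cl <- greedy_cluster(used, ccfg)
  gated <- gate_clusters(cl, total_reads = nrow(used),
                         min_cluster_fraction = config$min_cluster_fraction)

  q <- mean_read_quality(used)
  cons_rows <- lapply(gated$cluster_id, function(cid) {
    members <- which(cl$assignments$cluster_id == cid)
    members <- members[order(-q[members], members)]
    poa_members <- head(members, config$poa_max_reads)
    data.frame(cluster_id = cid,
               consensus = poa_consensus(used$bases[poa_members],
                                         config$match, config$mismatch,
                                         config$gap),
               n_reads = length(members),
               mean_quality = mean(q[members]),
               stringsAsFactors = FALSE)
  })
  cons <- do.call(rbind, cons_rows)
  merged <- merge_rc_consensus(cons, config$merge_identity)
  gq <- tapply(merged$mean_quality * merged$n_reads, merged$group_id, sum) /
    tapply(merged$n_reads, merged$group_id, sum)
  maj <- select_majority(merged, total_reads = nrow(used), group_quality = gq)

  draft <- merged$consensus[merged$cluster_id == maj$anchor_cluster]
  pol_bases <- character(0)
  for (cid in maj$cluster_ids) {
    members <- which(cl$assignments$cluster_id == cid)
    b <- used$bases[members]
    if (merged$orientation[merged$cluster_id == cid] == "rc") {
      b <- reverse_complement(b)
    }
    pol_bases <- c(pol_bases, b)
  }
  pol <- polish_consensus(draft, pol_bases, rounds = config$polish_rounds,
                          match = config$match, mismatch = config$mismatch,
                          gap = config$gap)
  trim <- trim_primers(pol$consensus, primers[1], primers[2],
                       config$max_primer_edits)

  report <- NULL
  if (!is.null(references)) {
    report <- identity_to_reference(trim$consensus, references, sample_label)
    report$fraction_reads_clustered <- maj$fraction
    report <- evaluate_criteria(report, config$min_identity,
                                config$expected_length, config$length_tol,
                                config$min_fraction)
  }
  list(status = "ok",
       n_filtered = nrow(filtered), n_used = nrow(used),
       clusters = cl, gated = gated, merged = merged, majority = maj,
       fraction_reads_clustered = maj$fraction,
       n_supporting = maj$n_reads,
       consensus = trim$consensus,
       consensus_untrimmed = pol$consensus,
       primer_trimmed = c(fwd = trim$trimmed_fwd, rev = trim$trimmed_rev),
       polish_rounds_used = pol$rounds_used,
       report = report)
}

#' Run the full barcoding pipeline
#'
#' Demultiplex -> filter -> (optional) subset -> cluster -> gate -> POA
#' consensus -> reverse-complement merge -> majority selection -> pileup
#' polishing -> primer trimming -> identity report, per sample. A failure in
#' one sample (for example, no reads surviving the filter) marks that sample
#' failed and leaves the others untouched. Given identical inputs, config
#' and seed the run is fully deterministic.
#'
#' @param reads a [read_set()] or a FASTQ path.
#' @param panel dual-index panel (see [validate_panel()]).
#' @param primers primer pair (a `reference_set` or `c(fwd, rev)`).
#' @param references optional [reference_set()] of barcode references; when
#'   supplied, each sample gets an identity report.
#' @param config a [pipeline_config()].
#' @param outdir optional directory for per-sample artifacts (demultiplexed
#'   and filtered FASTQ, cluster table, consensus FASTA, reports, run log).
#' @return A list of class `pipeline_run`: `samples` (per-sample results),
#'   `assignments`, `summary` (one row per sample), `config`.
#' @export
run_pipeline <- function(reads, panel, primers, references = NULL,
                         config = pipeline_config(), outdir = NULL) {
  if (is.character(reads)) reads <- read_fastq(reads)
  panel <- validate_panel(panel)
  primers <- .as_primer_pair(primers)
  dm <- demux_reads(reads, panel, mode = config$demux_mode, primers = primers,
                    min_score = config$min_score,
                    max_index_edits = config$max_index_edits,
                    max_primer_edits = config$max_primer_edits,
                    search_window = config$search_window)
  fcfg <- filter_config(config$min_mean_q, config$min_len, config$max_len)

  samples <- list()
  for (si in seq_len(nrow(panel))) {
    s <- panel$sample_label[si]
    sample_reads <- dm$samples[[s]]
    res <- tryCatch({
      if (is.null(sample_reads) || !nrow(sample_reads)) {
        stop("no reads demultiplexed to this sample")
      }
      flt <- filter_reads(sample_reads, fcfg)
      out <- .analyze_filtered(flt$retained, primers, references, config,
                               config$subset_size,
                               subset_seed = config$seed + si,
                               sample_label = s)
      out$n_demuxed <- nrow(sample_reads)
      out$rejected <- flt$rejected
      out$stats <- compute_stats(list(demultiplexed = sample_reads,
                                      filtered = flt$retained))
      out
    }, error = function(e) {
      list(status = "failed", message = conditionMessage(e),
           n_demuxed = if (is.null(sample_reads)) 0L else nrow(sample_reads))
    })
    samples[[s]] <- res
  }

  run <- structure(list(samples = samples, assignments = dm$assignments,
                        summary = .run_summary(samples),
                        config = config), class = "pipeline_run")
  if (!is.null(outdir)) .write_artifacts(run, dm, outdir)
  run
}

.run_summary <- function(samples) {
  rows <- lapply(names(samples), function(s) {
    r <- samples[[s]]
    ok <- identical(r$status, "ok")
    data.frame(
      sample_label = s, status = r$status,
      n_demuxed = if (!is.null(r$n_demuxed)) r$n_demuxed else NA_integer_,
      n_filtered = if (ok) r$n_filtered else NA_integer_,
      n_used = if (ok) r$n_used else NA_integer_,
      n_supporting = if (ok) r$n_supporting else NA_integer_,
      fraction_reads_clustered = if (ok) r$fraction_reads_clustered else NA_real_,
      consensus_length = if (ok) nchar(r$consensus) else NA_integer_,
      percent_identity = if (ok && !is.null(r$report))
        r$report$percent_identity else NA_real_,
      matching_length = if (ok && !is.null(r$report))
        r$report$matching_length else NA_integer_,
      best_reference = if (ok && !is.null(r$report))
        r$report$best_reference else NA_character_,
      pass = if (ok && !is.null(r$report)) r$report$pass else NA,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Amplicon consensus pipeline run\n")
  cat(sprintf("  %d read(s) demultiplexed across %d sample(s); mode: %s\n",
              sum(!is.na(x$assignments$sample_label)),
              length(x$samples), x$config$demux_mode))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

.write_artifacts <- function(run, dm, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, path) write.table(df, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE)
  tsv(run$assignments, file.path(outdir, "assignments.tsv"))
  tsv(demux_summary(run$assignments), file.path(outdir, "demux_summary.tsv"))
  tsv(run$summary, file.path(outdir, "run_summary.tsv"))
  write_config(run$config, file.path(outdir, "config.json"))
  for (s in names(run$samples)) {
    r <- run$samples[[s]]
    d <- file.path(outdir, s)
    dir.create(d, showWarnings = FALSE)
    if (!is.null(dm$samples[[s]])) {
      write_fastq(dm$samples[[s]], file.path(d, "demultiplexed.fastq"))
    }
    if (!identical(r$status, "ok")) next
    tsv(r$clusters$assignments, file.path(d, "clusters.tsv"))
    tsv(r$merged[, c("cluster_id", "n_reads", "group_id", "orientation",
                     "is_anchor")],
        file.path(d, "consensus_groups.tsv"))
    cons <- r$consensus
    names(cons) <- paste0(s, "_consensus")
    write_fasta(cons, file.path(d, "consensus.fasta"))
    if (!is.null(r$report)) {
      tsv(r$report, file.path(d, "report.tsv"))
      jsonlite::write_json(as.list(r$report), file.path(d, "report.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  invisible(outdir)
}

#' Benchmark the pipeline over subset sizes and demultiplexing modes
#'
#' Runs the downstream pipeline on seeded random subsets of each sample's
#' filtered reads, for every combination of subset size and demultiplexing
#' mode, and tabulates the identification metrics -- the read-depth
#' titration used to ask how few reads still give a correct, full-length
#' barcode.
#'
#' @param reads,panel,primers,references,config as in [run_pipeline()].
#' @param subset_sizes integer vector of subset sizes (default from
#'   `config$subset_sizes`). An empty grid returns an empty table.
#' @param modes demultiplexing modes to benchmark.
#' @return A data frame of class `benchmark_table`, one row per
#'   mode x subset x sample, with identity, matching length, supporting-read
#'   count and clustered-read fraction; `summary` attribute holds mean/sd by
#'   mode x subset.
#' @export
run_benchmark <- function(reads, panel, primers, references = NULL,
                          config = pipeline_config(),
                          subset_sizes = config$subset_sizes,
                          modes = c("edit", "score")) {
  if (is.character(reads)) reads <- read_fastq(reads)
  panel <- validate_panel(panel)
  primers <- .as_primer_pair(primers)
  empty <- data.frame()
  if (!length(subset_sizes) || !length(modes)) {
    return(structure(empty, class = c("benchmark_table", "data.frame")))
  }
  fcfg <- filter_config(config$min_mean_q, config$min_len, config$max_len)
  rows <- list()
  for (mode in modes) {
    dm <- demux_reads(reads, panel, mode = mode, primers = primers,
                      min_score = config$min_score,
                      max_index_edits = config$max_index_edits,
                      max_primer_edits = config$max_primer_edits,
                      search_window = config$search_window)
    for (si in seq_len(nrow(panel))) {
      s <- panel$sample_label[si]
      sample_reads <- dm$samples[[s]]
      if (is.null(sample_reads) || !nrow(sample_reads)) next
      filtered <- filter_reads(sample_reads, fcfg)$retained
      for (k in subset_sizes) {
        res <- tryCatch(
          .analyze_filtered(filtered, primers, references, config,
                            subset_size = k,
                            subset_seed = config$seed + si * 1000L + k,
                            sample_label = s),
          error = function(e) list(status = "failed",
                                   message = conditionMessage(e)))
        ok <- identical(res$status, "ok")
        rows[[length(rows) + 1L]] <- data.frame(
          mode = mode, subset_size = k, sample_label = s,
          status = res$status,
          n_filtered = nrow(filtered),
          n_used = if (ok) res$n_used else NA_integer_,
          n_supporting = if (ok) res$n_supporting else NA_integer_,
          fraction_reads_clustered = if (ok) res$fraction_reads_clustered
            else NA_real_,
          percent_identity = if (ok && !is.null(res$report))
            res$report$percent_identity else NA_real_,
          matching_length = if (ok && !is.null(res$report))
            res$report$matching_length else NA_integer_,
          consensus_length = if (ok) nchar(res$consensus) else NA_integer_,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  num <- c("percent_identity", "matching_length", "n_supporting",
           "fraction_reads_clustered")
  ok <- out$status == "ok" & !is.na(out$percent_identity)
  if (any(ok)) {
    agg_mean <- aggregate(out[ok, num], by = out[ok, c("mode", "subset_size")],
                          FUN = mean)
    agg_sd <- aggregate(out[ok, num], by = out[ok, c("mode", "subset_size")],
                        FUN = sd)
    names(agg_sd)[-(1:2)] <- paste0(num, "_sd")
    attr(out, "summary") <- merge(agg_mean, agg_sd,
                                  by = c("mode", "subset_size"))
  }
  structure(out, class = c("benchmark_table", "data.frame"))
}

#' @export
print.benchmark_table <- function(x, ...) {
  cat("Pipeline benchmark (one row per mode x subset x sample)\n")
  print(as.data.frame(x), row.names = FALSE)
  s <- attr(x, "summary")
  if (!is.null(s)) {
    cat("\nMean (sd) by mode x subset:\n")
    print(s, row.names = FALSE)
  }
  invisible(x)
}
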