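---
title: "Methods: amplicon barcoding consensus from noisy long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amplicon barcoding consensus from noisy long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
decisions behind `nanobarcode`, in the spirit of a methods section: what
each stage assumes, why the defaults are what they are, and where the
design was genuinely open.

## The problem and its assumptions

The input is a pool of basecalled long reads from dual-indexed amplicon
libraries: every molecule is
`forward_index + forward_primer + insert + rc(reverse_primer) +
rc(reverse_index)`, where the insert is a species-diagnostic barcode
(nominally 421 bp of mitochondrial cytochrome b) and `rc()` denotes reverse
complement. Reads arrive in both orientations, at a mean read quality near
Q10 (about 9% per-base error), with insertions and deletions concentrated
in homopolymer runs. The pipeline's job is to recover, per sample, a
consensus accurate enough for species assignment by sequence similarity
(>99% identity over ~421 bp).

Two assumptions matter throughout. First, one sample is expected to carry
one dominant barcode; mixtures appear only as contamination, which the
cluster-size gate and majority selection are designed to exclude, not to
resolve. Second, indexes and primers are short, unambiguous (`N`-free)
sequences whose panel members are mutually distant, so that edit-distance
thresholds have clean semantics.

## Demultiplexing

Each read end is searched (default window: 150 bases) for the appropriate
index by semi-global alignment (the index aligns end-to-end, gaps at the
window ends are free, unit edit costs). Both read orientations and every
panel pair are tried; the read is oriented so the forward index sits at the
5' end.

Two assignment modes are provided:

* **Score mode.** Per index, `score = 100 * (L - d) / L` with `d` the edit
  distance and `L` the index length; the pair score is the *worse* of the
  two indexes, both of which must be found, and assignment requires
  `score >= min_score` (default 99). With 24-nt indexes this demands exact
  matches of both indexes. On reads at ~9% per-base error only about
  `0.91^48` (roughly 1%) of true reads have two error-free indexes, so
  score mode at its default threshold is an aggressively conservative
  filter: very few, very clean reads. It is retained because that is what
  the score's definition implies, and a handful of clean reads still
  yields an accurate consensus — but it is not the default for full runs.
* **Edit mode** (the pipeline default). Both indexes must be located within
  `max_index_edits` (default 2); primers found just inside the indexes
  within `max_primer_edits` (default 11) are trimmed too, and an
  unlocatable primer is *retained* (under-trimming is preferred over the
  risk of cutting into the barcode). At the default error model this keeps
  roughly a third of true reads, which matches the heavy demultiplexing
  attrition this class of stringent workflows exhibits while leaving
  hundreds of reads for consensus building. Because the index panel here is
  user-supplied, the general-purpose edit mode is the natural default.

In both modes a read that fits two panel pairs equally well is left
unassigned; assigned reads therefore form a partition and cross-sample
leakage can only come from sequencing error, not from tie-breaking.

Primer location, both here and when trimming the final consensus, is
*anchored*: the search window is the primer length plus 8 bases and a hit
must start within 4 bases of the expected terminus. This matters: an
unanchored semi-global search with an 11-edit tolerance will "find" a
25-nt primer inside unrelated barcode sequence often enough to truncate a
correct consensus.

## Filtering and subsetting

Mean read quality is computed on the error-probability scale,
`Q = -10 log10( mean_i 10^(-q_i/10) )`, which is the quantity a quality
threshold is actually about; the arithmetic mean of Phred values would be
systematically higher and silently loosen the filter. Reads are kept iff
`Q >= 7` and the trimmed length lies in the inclusive window 321–521 bp
(the 421-bp target with a 100 bp buffer; inclusive endpoints take the
printed bounds at face value). Lengths are measured after trimming, since
the window is defined around the insert. Subsetting draws a uniform,
seeded sample without replacement; asking for more reads than exist
returns everything with a warning, so depth-titration grids can include
subset sizes larger than the data.

## Clustering

Reads are clustered greedily in decreasing-quality order using
lexicographic minimizers (k = 13, window w = 5). A read joins the first
cluster whose *profile* — the union of minimizers contributed by its
members, saturating after 100 contributors — contains at least
`min_shared_fraction` of the read's minimizers; otherwise it founds a new
cluster. Minimizers are strand-specific, so forward and reverse reads form
separate clusters by construction, exactly as strand-aware long-read
clusterers behave; the reconciliation happens later at the consensus-merge
stage.

The joining threshold is derived from the error model rather than tuned.
A k-mer survives uncorrupted in a read with probability about
`(1-e)^k ~ 0.29` at `e = 0.09`, `k = 13`, so a read shares roughly that
fraction of minimizers with a saturated same-template profile. Two
*templates* at 80% identity share `0.8^13 ~ 5%` of their k-mers, giving a
cross-template expectation near `0.016`. The default threshold 0.07 is the
geometric midpoint of the two regimes — far enough from both that binomial
fluctuations over the ~130 distinct minimizers of a 421-bp read rarely
cross it. (A threshold of one half, natural as it may sound, is
unattainable: even two error-free-template comparisons only reach ~0.29 at
this error rate, and two noisy reads share ~`(1-e)^{2k} ~ 8%`.)

Greedy founding inevitably fragments early — the first few comparisons are
read-versus-singleton-profile, the noisiest regime — so a deterministic
absorption pass follows: every read is re-examined against the final
profiles and moves to the *largest* cluster that clears the threshold
(ties to the lower cluster id). Same-template fragments collapse into the
dominant cluster; cross-template moves stay blocked by the threshold. The
pass is order-independent because sizes and profiles are frozen from the
greedy phase.

Clusters with strictly more than `min_cluster_fraction` (default 10%) of
the clustered reads are retained. The strict inequality is deliberate: a
cluster at exactly the threshold is dropped.

## Consensus: POA draft, merge, majority, polish

**Draft.** Each retained cluster's reads (up to `poa_max_reads = 500`,
highest quality first) are threaded progressively into a partial order
graph: a dynamic program over the graph's topological order aligns each
read (globally in the read, free graph ends), matched positions reuse
nodes, mismatches become ring alternatives of the same column, insertions
add nodes, and edges count traversals. Alignment scores default to
match +2, mismatch −4, gap −6 with two tie rules: equal-scoring alignments
prefer fewer gaps, and a real predecessor beats a fresh start. The gap
penalty is deliberately steeper than the mismatch penalty (as in the POA
engines used for amplicon consensus in practice): with gap = mismatch, a
one-base shift near a repeat that trades two mismatches for an
insertion–deletion pair is score-neutral and would scramble column
bookkeeping.

The draft is the path maximising the sum of re-centred column transitions
`8w − n` (aggregated over ring alternatives), where `w` is the number of
reads making the transition and `n` the number of reads. Re-centring kills
the length bias of a plain heaviest path — a split vote cannot be
harvested twice by a detour — and makes weakly supported end branches
drop out of the maximum-sum subpath on their own. The pivot at `n/8`
rather than `n/2` is an explicit asymmetry: a deletion bypass needs more
than ~62% of reads to enter the draft, while an insertion detour needs
only ~37%. Drafts therefore err long. The reason is the polishing step's
asymmetry: pileup voting removes an unsupported base with a simple
per-column plurality, but restoring a missing base requires insertion
votes to agree on a single junction, and in run-rich sequence a nearby
complementary indel lets the aligner absorb the discrepancy as a shifted
segment ("mismatch ladder"), scattering those votes. Giving polish
removal-work instead of restoration-work is what makes the combination
converge on the truth. For gap-free, equal-length inputs (no detours or
bypasses in the graph) the draft reduces exactly to per-column majority
voting, a property the test suite checks against a brute-force oracle over
hundreds of random instances.

**Merge.** Cluster drafts are grouped by single linkage when either the
direct or reverse-complement pairwise identity reaches
`merge_identity = 0.9`. Identity is matches divided by alignment length of
a free-end-gap global alignment, with end overhangs counted as alignment
columns, so length disagreement costs identity. Orientation parity is
propagated from each group's largest cluster so member reads can be
oriented consistently.

**Majority and polish.** The group with the most supporting reads wins
(ties to higher mean read quality); its fraction of the reads that entered
clustering is the reported support. All its reads, oriented to the anchor,
polish the anchor's draft: per-column plurality over `{A,C,G,T,deletion}`
(ties keep the draft), insertions accepted when more covering reads agree
on one inserted string than support none, columns spanned by at most half
the reads dropped (free-end alignment leaves ragged, weakly covered ends
that a local plurality must not extend). After the column votes converge,
a modal homopolymer run-length repair pass runs: each read casts one net
length vote per run (its insertions of the run base minus its deletions in
the run), and the run is re-emitted at the modal observed length, ties
keeping the draft. Modal — not majority — matters: a nine-base run at 9%
per-base deletion sees *some* deletion in more than half the reads, yet
nine remains the single most common observed length. Two polish rounds
(the default) are a fixed point on clean reads.

Neural network polishing, which the field often appends, is replaced by
this pileup voting by design: a self-contained package cannot carry
trained basecaller-specific weights, and at simulator error rates pileup
voting with the long-biased draft reaches the accuracy the reporting
thresholds require.

## Reporting

Primers (or their reverse complements) are trimmed off the final consensus
with the anchored search described above; an end without a locatable
primer is left untouched and flagged. Identification replaces a database
search with exhaustive free-end-gap global alignment against the supplied
reference panel — reference sets here are tiny, and this keeps identity
semantics identical to the merge stage. The report carries percent
identity (`100 · matches / alignment_length`), matching length (identical
aligned positions — so "421 of 421" means a perfect full-length match),
consensus length, and the supporting-read fraction. The decision rule:
identity strictly above 99, matching length within ±5 bp of the expected
421 (the operational meaning of "approximately full length"), and a
fraction below 0.75 raises an *investigate* flag without failing the
identification — minority clusters may hold contaminants worth a look.

## The simulator: what it emulates, and what it does not

`simulate_reads()` draws, per template position in order: deletion (with
probability `del_rate`, multiplied by `homopolymer_del_multiplier` inside
runs of length ≥ `hp_min_len`), else substitution (`sub_rate`), and an
insertion of a uniform random base after the position (`ins_rate`).
Deletion and substitution are mutually exclusive per position, so realized
class counts are exactly binomial at the configured rates — which is what
the simulator's statistical tests assert. Per-base quality is constant
within a read, drawn once from `Normal(mean_read_quality, quality_sd)`
clamped to [2, 40]; real basecallers report per-base structure, but
read-level means are all the downstream filter consumes. Defaults
(`sub = ins = del = 0.03`, multiplier 3, mean Q 10.5, sd 1.5) encode a
~9% total error rate consistent with a Q10.5 mean; the per-class split is
a modelling choice, since only the aggregate is observable from read
quality. Strand is forward with probability `strand_fraction` (default
0.5), an optional `chimera_rate` concatenates two templates to exercise
the length filter, and `mix_contamination()` swaps an exact count of
same-index contaminant reads into a sample, shuffled deterministically.

What passing tests on simulated data do *not* show: robustness to
basecaller-specific error profiles (context-dependent substitutions,
quality–error correlation along the read), to adapter chimeras other than
the simple two-template concatenation, to length variation of the true
barcode across taxa, or to genuine mixtures. The bundled references are
synthetic stand-ins with the right lengths and repeat structure, not real
barcode sequences.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on simulated data at
desk scale: 500-read clean samples and 1000-read contaminated samples for
end-to-end checks, a 2000-read simulation for the subset-size grid
(100/500/5000, where a subset larger than the data uses all reads), a few
hundred reads for statistical checks on the error model, and
50–200 random instances for the column-majority oracle. These sizes keep a
full run in minutes while leaving the binomial margins the derivations
above rely on. Every stochastic step takes an explicit seed; a rerun with
the same inputs, configuration and seed is byte-identical, and the
acceptance script derives all its seeds from a single `--seed` argument.

## Known limitations

* Score-mode demultiplexing at its default threshold is essentially an
  exact-match filter at nanopore error rates; use edit mode unless you
  specifically want that stringency.
* The POA draft is intentionally not the final consensus; its raw accuracy
  on noisy reads is draft-grade (residual errors sit in homopolymer runs,
  the platform's dominant error mode) and only the polished consensus
  carries the accuracy guarantees. Likewise, exact strand symmetry holds
  for the polished consensus, not the tie-broken draft.
* Run-length repair handles homopolymers; short tandem repeats (e.g.
  dinucleotide motifs) still rely on the draft being long-biased plus
  column voting.
* One barcode per sample is assumed; mixed-species samples are flagged at
  best (low supporting fraction), never resolved.
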