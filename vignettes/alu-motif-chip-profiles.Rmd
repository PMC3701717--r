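---
title: "Alu motif scanning, occurrence bootstrap and anchored ChIP profiles"
author: "aluscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alu motif scanning, occurrence bootstrap and anchored ChIP profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aluscan)
```

## The scientific problem

Long non-coding RNAs can regulate distant genes in trans by steering
chromatin regulators — in particular Polycomb repressive complexes (PRC1/2,
with members such as CBX7 and SUZ12) — to target promoters. One proposed
addressing mechanism runs through Alu repeats: short interspersed elements
present in roughly a million copies per human genome, of which the Alu-DEIN
subfamily contributes a 25-nt core motif
(`CACGCCTGTAATCCCAGCACTTTGG`). Two quantitative questions follow:

1. Is the Alu motif differentially abundant in promoters of genes that
   respond to the regulator (up- or down-regulated) versus genes that do
   not?
2. Is Polycomb ChIP-seq signal spatially organised around the motif — and
   does that organisation survive the read-mapping ambiguity that
   repetitive elements inevitably cause?

`aluscan` implements the full computational chain for both questions, plus
a synthetic-data generator that lets every step be validated closed-loop
against planted ground truth.

## The motif model and its exact p-values

The motif is a position weight matrix (PWM): per-column base probabilities
$p_{b,j}$ with an additive pseudocount, scored against a window $w$ as the
log-odds sum $S(w) = \sum_j \log_2 (p_{w_j,j} / \pi_{w_j})$ with
background $\pi$. A window's *motif p-value* is the probability that an
i.i.d. background window scores at least as high. `exact_pvalues()`
computes this distribution exactly: each log-odds cell is quantized to
integer multiples of a granularity (0.01 log2 units by default, rounding
half away from zero) and the distribution of the window score is built by
columnwise convolution over the integer score lattice. The table is exact
for the quantized matrix — no normal or large-deviation approximation —
and tests verify it against exhaustive enumeration of all $4^w$ windows
for widths up to 6.

Numerical choices worth stating:

* **Granularity 0.01 log2.** The DP table stays a few thousand bins wide
  for a width-25 motif, while the quantization error (at most 0.125 log2
  over 25 columns) is far below the score differences that matter at the
  p = 1e-4 threshold.
* **Scan scores are quantized.** `scan_motif()` reports the quantized
  score so that score and p-value are mutually consistent;
  `score_window()` returns the unquantized sum.
* **N is neutral.** A non-ACGT base contributes 0 log-odds — it neither
  fakes a match nor destroys an otherwise strong window, the right
  behaviour at repeat-masked bases.
* **Zero-probability cells** (possible only at pseudocount 0) score
  $-\infty$; their background mass sits below every finite score, so the
  tail at the lowest finite score is less than 1 while anything below it
  has p-value 1.
* **Strands.** Scanning runs the PWM and its reverse complement over the
  forward strand; minus-strand hits are reported in forward coordinates
  (0-based half-open, BED-compatible). The p-value is one-strand, so a
  both-strand scan of length $L$ expects $2 L p$ false positives — the
  calibration the test suite checks empirically.

The default scan threshold is p ≤ 1e-4, the conventional single-motif
scanning stringency. The pseudocount default is 0.1 and the background
uniform; neither is critical at this threshold, and both are exposed.

## Transcript classification and promoter groups

Expression input is a transcripts × samples intensity matrix with case
(over-expressing) and control (vector) lines. The average fold change is
the *mean of per-line ratios* against the mean control intensity —
per-line gene lists exist in this design, so per-line ratios are the
primitive, and averaging them is the natural aggregate. The filter is a
pure threshold rule: average fold change > 2 is "up", < 0.5 is "down",
everything else — boundaries included — is "not" regulated. There is
deliberately no variance model: the classification this pipeline feeds on
is a fold-change filter, not a differential-expression test.

Promoters are the 5 kb upstream of the TSS, strand-aware, TSS excluded
for plus-strand genes (`[tss - 5000, tss)`), reverse-complemented
`[tss, tss + 5000)` for minus-strand genes; truncations at contig ends
are kept and flagged rather than discarded. Gene-set enrichment of the
regulated class is a one-sided Fisher exact test (hypergeometric upper
tail) on user-supplied sets; raw p-values by default, Benjamini–Hochberg
on request.

## The occurrence bootstrap

Comparing motif counts between promoter groups of very different sizes is
confounded by length and composition; the bootstrap used here resamples a
fixed amount of sequence per group instead:

1. chop every promoter into consecutive 100-nt pieces (remainders
   dropped);
2. per repetition, draw 250 chops per group uniformly *without*
   replacement and sum their both-strand motif hits at p ≤ 1e-4;
3. repeat 1000 times, giving one occurrence total per repetition;
4. compare groups with the two-sample Kolmogorov–Smirnov test
   (asymptotic p — with 1000 values per side the exact test is
   unnecessary).

Per-chop hit counts are computed once and cached; a test verifies that
bootstrapping cached counts is draw-for-draw identical to re-scanning
every draw. Draws are independent across repetitions, and each group's
draw stream restarts from the same seed, so two groups holding the same
chop multiset produce identical vectors — a useful determinism contract.

One statistical subtlety: repetition totals drawn from a single finite
chop pool are exchangeable but not independent of the pool's sampling
noise. When two groups are drawn from *disjoint* pools of the same
population, the pools themselves differ by chance, which pushes the KS
test slightly above nominal rejection at small pool sizes. The bundled
calibration test therefore uses the realistic pool size (50,000 chops per
group, i.e. 1,000 chopped 5-kb promoters) with background-rate Poisson
counts, 300 repetitions and 200 simulated pairs, and requires the
rejection rate at p < 0.05 to stay within 0.05 ± 0.03.

The per-5-kb occurrence summary is total hits divided by total promoter
length, scaled to 5 kb — a mean over both strands. Whether one counts all
hits or only hits matching planted truth is explicit in the API
(`truth_matched_hits()` deduplicates to the best hit per planted copy).

## ChIP coverage, read policies and anchored profiles

Alignment records carry `n_best`, the number of equally best placements
of the read. Two policies turn records into weighted placements:

* **multi** — every best placement is kept at weight $1/n_{best}$, so each
  read contributes total mass 1. This preserves the semantics of
  "reads per million mapped reads": RPM normalization divides by total
  retained mass and multiplies by $10^6$. A full-weight variant exists
  for sensitivity analysis but is not the default, because it double
  counts reads and breaks RPM semantics.
* **unique** — only reads with a single best placement survive, at
  weight 1.

Coverage is a per-base pileup of placement weights over the read span (no
fragment extension by default; an extension length would be a
config knob, but none is assumed). Meta-profiles sample the track at
oriented offsets around anchors: for a "+" anchor at $p$, offset $o$
reads base $p + o$; for a "−" anchor, base $p - o$. The anchor of a motif
is its start on its own strand. Offsets beyond a contig end drop that
anchor *for that offset only*. The peak-offset estimate smooths the
profile with a truncated moving average (25 points by default, matching
base resolution over a ±10 kb span) and returns the argmax, ties
resolving to the smallest absolute offset, with an explicit flatness flag
for degenerate tracks.

The policy contrast is the scientific point: when enrichment sits in
multi-copy repeat families, the unique policy discards exactly the reads
that carry the signal, flattening the peak downstream of the motif; the
multi policy recovers it. The invariant suite checks both directions —
multi peak height strictly above unique at the planted offset whenever
families exist, and bitwise-identical tracks when the family fraction
is zero.

## What the synthetic generator emulates — and what it does not

The generator produces every input the pipeline consumes, under one
master seed with fixed per-stage offsets (byte-identical reruns):

* **Promoters.** Three groups (up / down / not), 1,000 × 5 kb each by
  default. Planted Alu copies per promoter are Poisson with group means
  of 4, 4 and 6 per 5 kb — the depletion geometry the analysis is meant
  to detect. Copies are full 300-bp repeat templates (core at offset
  100), placed uniformly among non-overlapping configurations (sampled
  exactly via the order-statistics construction — k offsets drawn in the
  free space and spread by the cumulative copy length — rather than by
  per-copy rejection, which starves at high densities), strands uniform,
  1% per-base divergence.
* **Repeat families.** 20% of copies form byte-identical families of
  three, members in distinct promoters — inter-locus ambiguity mirroring
  genomic Alu dispersal. Family membership, not sequence identity search,
  determines `n_best` in the simulated alignments.
* **ChIP reads.** 200,000 reads of 36 bp; half enriched. An enriched
  read picks a random planted copy and centres
  Normal(+150 bp, sd 40) downstream of the core start along the copy's
  orientation; a family read yields one record per member at the
  homologous position. The Gaussian shape is a modelling choice — only
  the peak position is a target quantity, and recovery tolerates ±25 bp.
  Out-of-bounds reads are resampled, never truncated.
* **Expression.** Log-normal baseline (meanlog log 100, sdlog 1), fold 3
  (log2 effect 1.585) for the 10% up / 10% down planted transcripts,
  multiplicative log2-normal noise of 0.2 — chosen so that recovery is
  high but not trivially perfect (the suite requires ≥ 95%).

Not emulated: sequencing errors and quality scores, paired ends, GC or
mappability bias, higher-order background composition (the background is
i.i.d. at GC 0.41 — the analysis contrasts motif against background, so
Markov structure would add realism but not discrimination), array-style
intensity artefacts, and genome-scale contig lengths. Passing tests on
this generator therefore demonstrate that the *machinery* is correct and
that the planted geometry is recoverable at realistic sizes; they do not
certify performance on real libraries with alignment artefacts.

## Problem sizes and runtime

The closed-loop acceptance checks run the generator at its defaults
(3,000 promoters, 15 Mb scanned on both strands, 150,000 chops, 200,000
reads); this completes in a few minutes on one core. Unit and property
tests use scaled-down instances (tens of promoters, thousands of reads)
chosen to keep the whole suite under a few minutes while leaving every
statistical check adequately powered.

## Design decisions that were genuinely open

* **Bootstrap compares repetition totals**, not per-chop counts: one
  repetition yields exactly one number, which is what "repeated 1000
  times" naturally produces, and totals are the quantity with a stable
  null under fixed draw size.
* **KS via `stats::ks.test`** (asymptotic): base R is the canonical
  implementation of this test; the test suite cross-checks D against a
  brute-force ECDF supremum.
* **Promoter definition** (5 kb upstream, strand-aware) is exposed as a
  span parameter rather than hard-coded.
* **"Not regulated" is the full complement** of up ∪ down — no inner
  neutral band — matching a two-threshold partition.
* **The orchestration layer is a function, not a shell tool.**
  `run_pipeline()` takes a YAML-loadable config and writes all
  intermediates (FASTA/BED/TSV/WIG/JSON) plus a machine-readable report;
  an R analysis package is driven from R, and wrapping stage subcommands
  in a shell dispatcher would only duplicate the function surface.
* **The 48-bp mutagenesis motif** is a synthetic stand-in embedding the
  25-nt core in Alu-consensus context; only the core is public. The
  mutagenesis operator substitutes exactly `round(fraction × length)`
  positions, so severities 25%, 33% and 100% of 48 give Hamming
  distances 12, 16 and 48.

## Known limitations

* Exact p-values assume an i.i.d. background; a composition-matched
  higher-order background would shift absolute p-values (not the group
  contrast).
* The multi policy's 1/k weighting treats all best placements as equally
  likely; no mapping-quality model is used.
* The KS p-value underflows to 0 for strongly separated groups — it is a
  bound, not a measurable quantity, below ~1e-300.
* `estimate_peak_offset` reports a single global maximum; multi-modal
  profiles (e.g. wave-shaped TSS occupancy) need the full profile, which
  every API returns alongside the summary.
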