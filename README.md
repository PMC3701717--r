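# aluscan

Alu repeats carry a 25-nt core motif (`CACGCCTGTAATCCCAGCACTTTGG`, the
Alu-DEIN class) that appears to organise where Polycomb repressive
complexes (SUZ12, CBX7) bind chromatin, and long non-coding RNAs can
exploit this addressing to regulate gene networks in trans. Testing that
idea computationally needs three pieces that are each easy to get subtly
wrong:

1. **Motif statistics** — scanning promoters with a position weight
   matrix whose p-values are exact: for a window score
   `S(w) = Σ_j log2(p(w_j, j) / π(w_j))`, the p-value is
   `P(S(background window) ≥ s)`, computed by dynamic programming
   (columnwise convolution over a quantized score lattice), not by
   approximation. Scanning covers both strands at the conventional
   threshold p ≤ 1e-4.
2. **A fair group comparison** — promoter sets of different sizes are
   compared by a bootstrap: promoters are chopped into 100-nt pieces, 250
   chops per group are drawn (without replacement) and their hits summed,
   1000 times; the per-repetition totals of two groups are compared with
   the two-sample Kolmogorov–Smirnov test. Densities are additionally
   summarised as occurrences per 5 kb of promoter.
3. **Repeat-aware ChIP-seq signal** — reads that map equally well to k
   loci are either all kept at weight 1/k ("multi" policy) or discarded
   ("unique" policy); coverage is RPM-normalized
   (`raw × 10^6 / total retained read mass`) and averaged in oriented
   windows (±10 kb, 1 bp resolution) around motif anchors, so a peak "150
   bp downstream of the motif" means downstream in each motif's own
   orientation. Inside repeat families, the unique policy deletes exactly
   the reads carrying the signal — the policy contrast is the point.

`aluscan` implements all three for R users working in regulatory
genomics, together with transcript classification by average fold change
(> 2 up, < 0.5 down versus vector control), strand-aware promoter
extraction, Fisher-exact gene-set enrichment, and a synthetic-data
generator that plants all of the above — Alu copies at chosen densities,
byte-identical multi-mapping repeat families, reads enriched at a chosen
offset, regulated transcripts at a chosen fold — so the whole pipeline is
validated closed-loop against ground truth.

## Worked example

Generate a grouped promoter set, scan it, run the occurrence bootstrap
and recover the planted ChIP peak:

```r
library(aluscan)

cfg <- simulation_config(seed = 42,
                         n_promoters = c(up = 200L, down = 200L, not = 200L))
template <- make_alu_repeat(alu_core(), divergence = 0, seed = 43)
ps <- generate_promoter_set(cfg, template)
ps
#> promoter_set: 600 sequences (down=200, not=200, up=200); 2791 planted truth intervals

pwm <- default_alu_pwm()
hits <- scan_motif(ps$sequences, pwm, p_threshold = 1e-4)
matched <- truth_matched_hits(hits, ps$truth)
round(occurrences_per_5kb(matched, ps), 2)
#>   up down  not
#> 4.14 3.92 5.89
```

The planted densities (4 per 5 kb in regulated, 6 in not-regulated
promoters) are recovered. The bootstrap separates the groups:

```r
chops <- chop_sequences(ps)
counts <- per_chop_hit_counts(chops, pwm)
bt <- bootstrap_occurrences(
  list(regulated = counts[chops$group %in% c("up", "down")],
       not = counts[chops$group == "not"]), seed = 44)
unlist(compare_occurrences(bt$totals$regulated, bt$totals$not))
#>     D     p
#> 0.575 0.000
```

D is the supremum ECDF difference between the two vectors of 1000
occurrence totals; p underflows to zero for this separation. Finally the
ChIP arm — multi-mapping policy, RPM coverage, direction-aware profile
around the planted motifs:

```r
aln <- simulate_chip_alignments(ps, cfg = cfg)
lens <- setNames(Biostrings::width(ps$sequences), names(ps$sequences))
trk <- coverage_track(resolve_placements(aln, "multi", validate = FALSE),
                      lens, normalize = "RPM")
prof <- anchored_profile(trk, anchors_from_intervals(ps$truth),
                         span = 10000, resolution = 1)
estimate_peak_offset(prof, smooth_window = 25)$offset
#> [1] 151
```

The smoothed profile peaks 151 bp downstream of the motif — the
generator planted 150. Under the unique policy the same profile's peak is
lower (61.5 vs 67.6 RPM here), the signature of enrichment sitting in
multi-mapping repeat families.

`run_pipeline(pipeline_config(...))` chains all stages (simulation,
classification, scanning, bootstrap, both-policy profiles, enrichment),
persists every intermediate (FASTA, BED, TSV, WIG, YAML) and writes a
JSON run report.

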