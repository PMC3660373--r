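# pairsv

Structural-variant (SV) discovery from paired-end sequencing data, combining
the two complementary signals a short-read library carries:

* **paired reads (PR)** — pairs whose mapped geometry contradicts the library
  (stretched insert, wrong order, wrong orientation, split across
  chromosomes) localize rearrangement junctions;
* **read depth (RD)** — windowed, GC-corrected coverage distinguishes
  copy-number gains and losses from balanced events.

Neither signal alone can interpret complex rearrangements: a cluster of
stretched-insert pairs may be a deletion, or one junction of a copy-paste or
cut-paste event. `pairsv` classifies every pair against an empirical
insert-size model, clusters same-category discordant pairs, predicts a
breakpoint interval for each cluster side, segments the depth signal, and
combines both to call five reported SV types — deletions, gains (tandem and
dispersed, direct or inverted), inversions, and intra-/inter-chromosomal
translocations — including the copy-paste/cut-paste combinations that single
clusters cannot resolve. With a matched normal sample, clusters shared with
the normal are subtracted first so every reported variant is somatic. A final
cascade filter routes unsupported calls through segmental-duplication,
simple-repeat and transposable-element annotation.

It is aimed at method developers and analysts who want an inspectable,
data-frame-native implementation of this calling strategy: every stage takes
and returns a tibble, so the pipeline can be run whole
(`run_sv_pipeline()`) or stage by stage with ordinary dplyr tools in between.

## The model in brief

For properly oriented pairs the insert length is `l = right − left`, the
distance between the two innermost aligned positions. From the empirical
distribution of `L` the concordance cut-offs are the percentiles

    LC = Q(α/2),   UC = Q(1 − α/2),        default α = 0.01,

which for Normal inserts sit 2.58 σ from the mean. Mapped pairs are then
`CONCORDANT`, `DISTANCE` (`l > UC`), `INSERT_DISCARDED` (`l < LC`), `ORDER`,
`ORI`, `CHRPOS` or `CHRPOSORI`. Same-category pairs *i*, *j* co-cluster when
both side anchors agree within `D = UC − LC`:

    |x(1)_i − x(1)_j| ≤ D   and   |x(2)_i − x(2)_j| ≤ D,

taking the transitive closure, and each cluster side yields a breakpoint
interval `[max x⁺, min x⁺ + UC)` (forward-supported) or
`(max x⁻ − UC, min x⁻]` (reverse-supported), so intervals tighten as support
`S` grows. Depth is counted per 100-bp window, GC-corrected by
`r̃ = r · m / m_GC`, stabilized as `y = √r̃ − √median(r̃)`, and segmented into
piecewise-constant runs; segment means beyond ±0.4 call GAIN/LOSS. A rule
table then combines clusters and segments (e.g. deletion = DISTANCE cluster
over a LOSS; inversion = forward-ORI and reverse-ORI clusters matching on both
sides with neutral depth; copy-paste = two clusters sharing an insertion locus
plus a GAIN over the source region).

## Worked example

Simulate a 100-kb reference, plant a 5-kb deletion, sequence the donor at
30×, and call variants:

```r
library(pairsv)

ref    <- simulate_reference(1, 100000, gc = 0.5, seed = 7)
donor  <- apply_svs(ref, sv_spec("DEL", "chr1", 40001, 45000))
pairs  <- simulate_read_pairs(donor, coverage = 30, seed = 8)

model  <- estimate_insert_model(pairs, alpha = 0.01)
tidy(model)
#>   library alpha    lc    uc median_l mean_l  sd_l n_obs low_n
#> 1 lib1     0.01   222   385      301   313.  253. 14227 FALSE

pairs  <- classify_pairs(pairs, model)
count_categories(pairs)
#>    category             n
#>  1 CONCORDANT       14087
#>  2 DISTANCE            70
#>  7 INSERT_DISCARDED    70
#>  9 ONE_END             23
#>  ...

clusters <- predict_breakpoints(cluster_pairs(pairs, model), model)
windows  <- transform_depth(gc_normalize(bin_reads(pairs, ref)))
calls    <- define_svs(clusters, segment_depth(windows))
dplyr::filter(calls, sv_class == "DEL")
#>   sv_class source_chrom source_lo source_hi s_total rd_state
#> 1 DEL      chr1             39992     45111      36 LOSS
```

The insert model recovers the simulated library (median 301 bp, cut-offs
222/385 ≈ ±2.58 σ); 70 pairs (≈ α/2 of the library plus the
deletion-spanning pairs) are DISTANCE; the cluster of 36 deletion-spanning
pairs predicts breakpoint intervals containing the true junctions
40000/45001, and the overlapping LOSS segment upgrades it from a putative to
a defined deletion. The same stages run from files via
`run_sv_pipeline(sv_config(tumour = "t.bam", normal = "n.bam",
reference = "ref.fa", somatic = TRUE))`, which writes a
`Results/{clusters,dofc,sv}` tree and a JSON run log; `exec/pairsv` wraps
`simulate` and `call` for shell use.

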