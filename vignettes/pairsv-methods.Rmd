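---
title: "Calling structural variants from paired-read and read-depth signals"
author: "pairsv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling structural variants from paired-read and read-depth signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairsv)
```

`pairsv` detects and interprets genomic structural variants (SVs) from
paired-end alignments by combining discordant read-pair (PR) geometry with a
GC-corrected read-depth (RD) segmentation. This vignette is the package's own
account of the method: the model and its assumptions, the tunable parameters,
what the synthetic-data generator does and does not emulate, the numerical
choices, and the design decisions taken where the design was genuinely open.

## The insert-size model

A sequencing library fragments DNA into inserts whose two ends are read
towards each other. After alignment, a properly oriented pair (leftmost read
forward, rightmost reverse, same chromosome) measures its insert as
`l = right − left`, the distance between the innermost aligned positions of
the two reads. The empirical distribution of `L` over such pairs defines the
concordance band: `LC` and `UC` are its `α/2` and `1 − α/2` percentiles
(linear interpolation between order statistics, i.e. `stats::quantile`
type 7 — deterministic and directly testable against a sort-based oracle).
The working assumption is that at least `1 − α` of pairs are concordant; if
`L` is Normal and `α = 0.01`, the cut-offs sit 2.58 standard deviations from
the mean, a closed form the test suite checks against large simulated
libraries.

Parameters: `alpha` (default **0.01**, dimensionless); estimation floor
`min_obs` (default **1000** pairs — below it the model is flagged
low-confidence); subsample cap `max_obs` (default **10⁶** pairs per library,
which bounds memory while leaving percentile noise negligible). When pairs
carry a `library` column the model is per library, since insert distributions
differ between libraries.

A consequence worth stating: the model is estimated from *all* properly
oriented pairs, including rearrangement-spanning ones. If discordant pairs
exceed roughly `α/2` of the library — e.g. an extremely SV-dense region —
the upper percentile can land inside the outlier cloud and inflate `UC`. At
realistic SV densities (thousands of events per gigabase) the contamination
is orders of magnitude below `α/2`; the package's simulated validation uses
event densities chosen to respect this assumption.

## Pair classification

Every mapped pair receives exactly one category from its geometry alone:
`CONCORDANT`, `DISTANCE` (`l > UC`), `INSERT_DISCARDED` (`l < LC` — evidence
of small insertions, which paired reads cannot size reliably; such pairs are
set aside and insertion calling is out of scope), `ORDER` (leftmost read
reverse), `ORI` (same strand), and `CHRPOS`/`CHRPOSORI` (different
chromosomes, opposite/same strand). Totality and uniqueness over the full
configuration space are enforced by an exhaustive enumeration test. Ties on
the leftmost coordinate are resolved as right order (deterministic, and the
tie is vanishingly rare). Mate-pair chemistry differs from paired-end only in
strand convention, so `library_type = "mate_pair"` flips both strands before
classification.

Pairs with mapping quality below `mapq_floor` (default **1**) are excluded:
multi-mappers placed at mapping quality 0 generate spurious discordant
geometry. The floor is configurable because the appropriate value depends on
the aligner's mapq semantics. One-end-anchored and fully unmapped pairs are
kept apart (`ONE_END`, `ORPHAN`); the anchored ends still contribute to read
depth.

## Clustering and breakpoint intervals

Same-category pairs supporting the same junction agree in position up to the
insert-length slack, so two pairs co-cluster when **both** side anchors (the
rightmost aligned position of the read on each side) lie within
`D = UC − LC` of each other; under Normal inserts `D` equals twice the
`1 − α/2` Normal quantile times σ. Opposite-strand categories anchor on their
forward and reverse reads; same-strand categories cluster forward–forward and
reverse–reverse pairs separately, with sides fixed by coordinate order.
Clusters are the *transitive closure* (single linkage) of this relation.

A design decision: the closure is computed with a coordinate-sorted sweep
plus union–find, enumerating candidate edges within a `D`-window of the sort
key. A sweep that extends a cluster only from its running anchor extrema is
faster but does not reproduce transitive closure in all configurations; since
the contract is exact closure semantics (and the suite verifies equality with
a brute-force oracle on hundreds of random instances), union–find was chosen.
Each pair belongs to exactly one cluster, and only clusters with
`S ≥ min_support` (default **2**) pairs are used further.

For a forward-supported side the junction lies right of every read end but
within `UC` of the earliest, giving the interval `[max x⁺, min x⁺ + UC)`;
reverse-supported sides mirror to `(max x⁻ − UC, min x⁻]`. Width is
`UC − (anchor spread)`, so intervals tighten as support grows. Clusters whose
two intervals overlap each other localize nothing useful and are flagged
unreliable; they are kept but demoted to undefined calls during
interpretation rather than deleted.

Confidence tiers annotate each cluster for downstream triage: a base-quality
tier (tier 1 if any member pair has both reads at phred ≥ 30, i.e. ≥ 99.9%
base-call accuracy; tier 2 at phred ≥ 20), a support tier (`high` [10, 50),
`medium` [5, 10), `low` below, and `special` when `S` is significantly larger
than mean coverage — operationalized as a one-sided Poisson tail
`P(X ≥ S) < 10⁻⁴` at rate equal to the mean coverage, since clusters far
above coverage usually sit in collapsed repeats), and a length tier for
intra-chromosomal clusters (`high` [1 kb, 1 Mb), `medium` [500 bp, 1 kb),
`special` outside those bins; inter-chromosomal clusters have no defined
length).

## Read depth

Each chromosome is tiled with non-overlapping windows (`window_size`, default
**100 bp** — small enough to resolve kilobase events at 30–45× while keeping
per-window Poisson noise workable; the value is configurable and nothing
downstream assumes it). Every mapped read increments exactly one window — the
one containing the largest share of its bases, with a 50/50 split going left
(deterministic tie-break). Window GC is annotated from the reference at 1%
resolution; windows over 50% `N` are masked.

Counts are GC-corrected by `r̃ᵢ = rᵢ · m / m_GC(i)` where `m` is the global
median and `m_GC` the median over windows sharing the GC bin; bins occupied
by fewer than `min_bin_windows` (default **50**) windows, or with zero
median, are masked — their medians are too unstable to correct with. The
corrected signal is variance-stabilized with a square-root transform shifted
by the global median, `y = √r̃ − √median(r̃)`, so diploid-typical windows
center on 0 and a copy-number step appears as a mean shift with roughly
constant noise. Segment means above **+0.4** / below **−0.4** (configurable)
are called GAIN / LOSS; at ≈ 30 reads per window a single-copy change shifts
`y` by `√(1.5 m) − √m ≈ 1.2` (gain) or `√(m/2) − √m ≈ −1.6` (loss), several
times the threshold.

Segmentation fits a piecewise-constant model per chromosome by bottom-up
backward elimination: every inter-window boundary starts as a candidate
breakpoint, and the weakest boundary — smallest
`|mean₁ − mean₂| / (σ̂ √(1/n₁ + 1/n₂))`, with σ̂ estimated robustly from
first differences (`MAD/√2`) — is merged away until every surviving boundary
scores at least `crit`. This is the backward-elimination stage of the
sparse piecewise-constant framework used for array CNV calling; the sparse
Bayesian initialization is omitted because the downstream contract (tiling
segments plus threshold state calls) does not require it, and elimination
from the full breakpoint set already meets the recovery targets. `crit`
(default **5**) was calibrated on a synthetic-step suite (10,050 windows, a
50-window event, signal-to-noise ratios 3–5, 20 seeds per condition), where
it recovers changepoints within ±2 windows at F1 ≥ 0.95 while keeping pure
noise at a single segment. Degenerate inputs are handled explicitly: a
constant signal yields one segment, and a noiseless signal keeps exactly its
non-zero jumps. Masked windows are removed from the fit, and segment bounds
meet halfway across masked gaps so segments always tile the chromosome.

## Interpreting variants

The interpreter consumes breakpoint-predicted clusters and state-called
segments. Multi-cluster combinations are matched before single-cluster rules,
greedily by descending total support — a deletion-like cluster that is really
one junction of a copy-paste or cut-paste event must not be consumed by the
simple rule first:

* **copy-paste gains** — two clusters sharing exactly one breakpoint locus
  (the insertion point) whose other two intervals delimit a source region
  with GAIN depth: `DISTANCE`+`ORDER` (same chromosome, direct),
  forward-`ORI`+reverse-`ORI` (inverted), two `CHRPOS` (another chromosome,
  direct), two `CHRPOSORI` (inverted);
* **cut-paste translocations** — the same insertion signature with NEUTRAL
  depth plus a `DISTANCE` cluster matching the two source junctions (the
  excision);
* **inversions** — forward- and reverse-`ORI` clusters matching on *both*
  sides, NEUTRAL depth;
* **single clusters** — `DISTANCE` over LOSS → deletion; `ORDER` over GAIN →
  tandem duplication; leftover `DISTANCE` → putative deletion; everything
  else → undefined, routed to the repeat filter.

Depth support means at least 50% of the candidate region lies in segments of
the required state and the region spans at least 3 windows; shorter regions
cannot carry RD evidence, so sub-window candidates rely on PR alone (an
unsupported short `DISTANCE` region stays putative). Both fractions are
configurable; the 50%/3-window defaults tolerate segment-boundary error of a
couple of windows without admitting contradictory states.

Breakpoint "equality" between clusters is interval overlap after symmetric
padding by `tolerance`. The prediction-interval formula assumes supporting
fragments no longer than `UC`, but categories without an insert-length cap
(`ORDER`, `ORI`, `CHRPOS`, `CHRPOSORI`) contain a tail fragment with
probability ≈ `S·α/2`, which shifts one interval edge past the junction by up
to the tail excess (tens of bp at σ = 30). Raw overlap (tolerance 0)
therefore fails to match genuinely co-located clusters a substantial fraction
of the time at `S ≈ 50`, so the default `tolerance` is **100 bp** — about
three insert-size standard deviations at the defaults, small against the
`≈ UC`-wide intervals. `match_breakpoints()` itself defaults to raw overlap
so the primitive stays neutral.

One genuine ambiguity is worth knowing about: a direct intra-chromosomal
cut-paste of segment `[a, b]` to position `p` produces exactly the same donor
sequence as moving `[b, p]` leftwards to `a`. Both descriptions are correct;
the caller reports whichever grouping carries more support.

With `somatic = TRUE`, tumour clusters are removed when **one** anomalous
pair of the same category in the matched normal would have joined the cluster
under the clustering bound. Raw normal pairs are used rather than normal
clusters (which would require `S ≥ 2`): a single normal read pair already
evidences germline presence, and the stricter test reduces false somatic
calls at the price of sensitivity to normal-sample contamination — the right
trade-off for a caller whose purpose is somatic specificity.

## The repeat filter

Calls that are RD- or combination-supported always pass. Putative and
undefined calls are tested breakpoint-interval against three user-supplied
BED tracks in a fixed cascade — segmental duplications, then simple repeats,
then transposable elements at > 90% identity to their family consensus
(RepeatMasker-style milli-divergence is converted as
`identity = 1 − divergence/1000`; a plain identity column is a config
switch). The whole predicted interval is tested, not its midpoint, because
the junction is only localized to the interval — the conservative choice.
Each filtered call lands in exactly one bin, filtered calls are reported
rather than discarded (repeat-mediated rearrangements are real), and passing
calls carry the identity of any overlapping TE.

## What the simulator emulates — and what it does not

The generator produces a uniform-composition reference (optionally with a
positional GC profile), applies any combination of the eleven rearrangement
classes with exact bookkeeping (donor length, junction coordinates, expected
anomaly categories), and draws fragments uniformly with Normal insert sizes,
emitting alignments analytically through the donor-to-reference block map.
`insert_mean`/`insert_sd` parameterize the insert as measured downstream (the
innermost-distance `l`), so a simulated library reproduces its nominal model
exactly. Reads straddling a junction are emitted unmapped, mimicking how an
aligner fails them (only split-read methods use those reads). Base qualities
are uniform (default phred 40) with an optional low-quality fraction to
exercise the quality tiers.

Deliberately not modelled: sequencing errors and SNVs, PCR duplicates,
mappability structure and repeats (every simulated read maps uniquely and
correctly), diploidy (events are homozygous: a deletion drops depth to ~0,
not half), chimeric fragments, and mate-pair circularization artefacts.
Passing the simulated suite therefore demonstrates the *logic* of the caller
— classification totality, closure clustering, interval calibration,
combination rules, somatic subtraction — under ideal mapping. It does not
demonstrate robustness to ambiguous alignment, which on real data is handled
by the mapq floor, the quality tiers and the repeat filter, and those can
only be calibrated on real genomes.

Default study conditions across the validation suite: 30× coverage, 100-bp
reads, 300 ± 30 bp inserts, α = 0.01, 100-bp windows; planted events are
5–6 kb on 100–500 kb chromosomes, with the multi-class scenario using two
500-kb chromosomes so that discordant pairs stay well below the `α/2`
contamination bound discussed above. These sizes keep every property
measurable at desk scale while matching the per-junction pair counts
(`S ≈ 40–50`) a 30× genome produces.

## Known limitations

* Homozygous simulation means heterozygous depth shifts (±0.15–0.2 on the
  `y` scale at 30×) are *not* what the ±0.4 thresholds are tuned for;
  detecting heterozygous CNVs by depth would need threshold and window
  adjustments.
* The insert model is a single empirical band; bimodal or heavily skewed
  libraries violate the ±percentile symmetry and should be split by library
  tag instead.
* Combination matching is pairwise/triple; nested or chained rearrangements
  sharing more clusters than the rule table expects degrade to their
  components.
* Balanced calls rest entirely on PR evidence; in repeat-dense regions their
  reliability is bounded by the repeat filter's annotation quality.
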