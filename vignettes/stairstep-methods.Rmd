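---
title: "Methods: broad-domain calling, differential density, and stairstep boundaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: broad-domain calling, differential density, and stairstep boundaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(stairstep)
```

This vignette documents the statistical model behind the package, the
parameters that matter and why their defaults are what they are, what the
synthetic data generator does and does not emulate, and the numerical and
design choices made where more than one defensible option existed.

## Data model

The atom is a *tag*: one sequenced paired-end insert, represented as an
unstranded genomic interval in 0-based half-open coordinates (so length =
end − start; conversion to the 1-based closed convention of
GenomicRanges happens only inside internal helpers). Tags are filtered
before any statistic: fragments longer than `max_insert` (default
1000 bp) are removed as library artifacts, then fragments with an exactly
identical (chrom, start, end) interval are collapsed to one. Exact
interval identity is the standard proxy for potential PCR duplicates of
unstranded inserts; strand is not modeled because an insert has no
meaningful strand. The order — insert filter first, then deduplication —
is one of two defensible orders; it is fixed so runs are reproducible,
and only affects the removal counts in the log, never the surviving set.
Multi-mapper removal is an alignment-time concern and is assumed done
upstream.

## Input normalization

For each position x, with ChIP coverage n(x), input coverage nᵢ(x), and
totals N, Nᵢ:

$$n_{norm}(x) = \frac{n(x)+1}{n_i(x)+1}\cdot\frac{N_i}{N}$$

The +1 pseudocounts keep the ratio defined and strictly positive where
either track is empty; the depth factor Nᵢ/N makes a ChIP track that is
distributed like its input normalize to ≈ 1 everywhere. Two points are
worth flagging:

* **N is total positional coverage** — the genome-wide sum of n(x),
  equal to the summed fragment lengths — *not* the fragment count. The
  two differ by the mean fragment length; with matched fragment-length
  distributions the distinction cancels, but it matters when ChIP and
  input libraries have different insert sizes.
* **Totals are genome-wide by default.** A per-chromosome option
  (`per_chromosome = TRUE`) is exposed for genomes where chromosomes are
  profiled at inhomogeneous depth; for the single-chromosome synthetic
  scenario the two are identical.

## Window enrichment and the empirical null

Normalized coverage is summed in sliding windows of size `w = 1000` bp
with step `s = 50` bp. Broad-domain marks justify the kilobase window;
the 50 bp step sets the boundary resolution of everything downstream.

The null distribution is *empirical*: every ChIP tag is redrawn at a
uniform start on its own chromosome and the full statistic — normalized
coverage against the *true* input, then window sums — is recomputed;
`rounds` (default 5) such randomizations are pooled into one sorted
reference. Design choices:

* Randomization preserves each tag's length by drawing starts on
  [0, L − length]. Redistributing single-position tags instead would
  change the marginal coverage distribution, and shortening
  edge-clipped tags would break the length-preservation property.
* The null is pooled genome-wide (exchangeability of windows) rather
  than per-window; a per-window null is unattainable from a handful of
  randomization rounds.
* The null passes through the same input normalization as the observed
  statistic, because the observed statistic is a ratio: randomizing the
  normalized track directly would not reproduce the pseudocount and
  depth-factor structure.

Window p-values use the add-one estimator
p = (1 + #{null ≥ obs}) / (1 + M), which is never zero and is slightly
conservative (super-uniform under the null). The significance cutoff
`alpha` is deliberately an explicit per-experiment choice (default
10⁻³): broad-domain callers are sensitive to depth and signal-to-noise,
and the cutoff belongs in the run configuration, not hidden in code.
Significant windows merge into maximal regions (`max_gap = 0` by
default: only overlapping or touching windows merge); with replicates,
only the base-level interval intersection of the two replicates' regions
survives. Interval intersection is the strictest reading of "significant
in both replicates"; a reciprocal-overlap matching rule would keep
near-miss extents that intersection drops.

### Calibration

Under uniformly placed tags the pipeline should call ≈ alpha of windows
significant. The test suite checks this on *disjoint* windows
(step = width): on the default overlapping grid, adjacent windows share
95% of their positions, so no binomial reference applies to the fraction
of significant windows. The calibration run uses ~10,000 disjoint 1 kb
windows on a 10 Mb chromosome and checks the empirical rate at
alpha = 0.01 against the exact binomial 99% interval.

## Differential density

Enriched regions from all conditions are merged into an aggregate set;
regions longer than `max_len = 50000` bp are split into
⌈L / max_len⌉ equal sub-regions (remainder base pairs go to the leftmost
sub-regions — a deterministic, order-free rule), so a single
condition-specific segment inside a very long domain is not averaged
away. Each region's *density* is total normalized coverage divided by
region length, averaged across replicates.

Densities for two conditions are fitted by ordinary least squares of y
on x with intercept; the residual SD uses the (n − 2) denominator, and
each region's Z-score is residual / residual SD, ranking candidates by
|Z| (`z_threshold` default 3). Choices and caveats:

* **Vertical residuals** are the default reading of "line of best fit";
  an orthogonal-distance option (`method = "orthogonal"`, total least
  squares) is exposed because the two differ when the slope is far from
  1.
* **The residual SD is the plain single-pass SD.** When a non-trivial
  fraction of the scatter is genuinely discordant, those points inflate
  the SD they are judged against, bounding the attainable |Z| at roughly
  √(n/k) for k outliers among n regions. On a desk-scale synthetic
  genome (≈ 20 scatter points, several of them locus sub-regions) this
  bound bites; on a genome-wide scatter with thousands of concordant
  regions it does not. A MAD-based robust SD (`robust = TRUE`) is
  exposed for the small-scatter case. No iterative outlier-exclusion
  refit is done: single-pass scoring is reproducible and sufficient for
  ranking.
* Degenerate inputs: constant x is an error (no identifiable line); a
  perfect fit (residual SD = 0) defines all Z = 0 and sets a
  `perfect_fit` flag rather than dividing by zero.

## Segmentation and boundary calling

Per-condition region calls over a locus are rasterized to the window
grid: a window is *covered* for a condition iff it lies entirely within
one of that condition's enriched regions. Within each condition, runs of
identical state shorter than `min_run` windows (default 5, ≈ 1.2 kb of
grid span) are absorbed into the flanking state — short flickers at
region edges are calling noise, not domains. Boundaries are the grid
coordinates between surviving runs; boundaries from different conditions
within one step of each other are reported once, at the position from
the more posterior condition (the posterior condition's transition is
the one that defines the regulatory step). Reported positions are grid
coordinates: precision is deliberately limited to the 50 bp step, and
in practice the dominant error is the ≈ w/2 edge bias of kilobase
windows straddling a sharp transition, so boundary errors of a few
hundred bp are expected and observed.

The nesting check (`check_nesting()`) verifies clear(c) ⊆ clear(c+1)
along the condition order and reports violating intervals — e.g. a
local re-methylation mound inside an otherwise clear domain — without
failing the run: violations are biology (or contamination) to look at,
not errors.

## The synthetic generator

`bxc_stairstep_scenario()` plants the reference geometry: a 380 kb locus
in a 2 Mb chromosome, four ordered conditions whose clear spans grow
from the locus-proximal edge (0, 92, 137, 173 kb — the fourth being
137 + 36), and twelve 15 kb enriched domains shared by all conditions
away from the locus. The shared domains carry varied enrichment
strengths (between half and five-thirds of the locus fold, all
collapsing to background when `fold = 1`) so that the differential
scatter spans a range of densities and the line of fit is identifiable;
a scatter where every region has the same density would make the
regression slope meaningless.

`generate_tags()` draws fragment starts from a piecewise-constant
Poisson intensity: background rate `chip_depth / fold` outside enriched
intervals and `chip_depth` (default 0.5 tags/bp) inside the locus
domains — "depth" here means the fragment rate inside enriched
intervals, so the stated fold (default 4) is exactly the
covered-to-background intensity ratio. Fragment lengths are truncated
normal (200 ± 50 bp on [50, 500]); the input is uniform at its own rate
(0.5 tags/bp); replicates are independent draws; all randomness fans out
deterministically from one root seed, so regeneration is byte-identical.

Anterior contamination mixes each condition's intensity with its
immediately anterior neighbour's at a weight f ∈ [0, 1): this emulates
imperfect sorting in which the contaminating population is the adjacent
anterior one. The consequence — a low residual level of signal over a
clear domain that rises with f but stays far below calling threshold —
is exactly the read-through behaviour the pipeline is designed to
tolerate at the enrichment-call stage, rather than model out by
deconvolution.

What the generator does **not** emulate: nucleosome-level structure
(placement is Poisson; the statistics operate at ≥ 1 kb), GC or
mappability bias, sharp point-source peaks, read-level sequence or
quality, and real inter-replicate overdispersion beyond Poisson. Tests
passing on this generator therefore demonstrate the statistics'
correctness and calibration under the stated model, not robustness to
every artifact of real libraries.

## Problem sizes and numerics

The test suite and the acceptance script run the full-scale scenario
(2 Mb, ≈ 0.5 M fragments/sample) for boundary recovery and contamination
read-through, a 10 Mb single-track run for calibration, and reduced
scales (0.05–0.25) for end-to-end and determinism checks; these sizes
give stable statistics while keeping a complete run in minutes on one
core. Window sums use cumulative sums (O(1) per window), so their
floating-point rounding differs from naive per-window summation in the
last bits; oracle comparisons use a 10⁻¹² relative tolerance, i.e.
agreement to double-precision accumulation order. Coverage is stored as
dense per-chromosome numeric vectors, adequate to ~50 Mb chromosomes;
larger genomes would need a run-length representation behind the same
position-query contract.

## Known limitations

* One pooled null assumes genome-wide exchangeability of windows;
  strong chromosome-scale coverage trends would violate it.
* The replicate rule (base-level intersection) is strict: a real domain
  whose two replicate calls misalign by more than the overlap erodes at
  the edges.
* Differential scoring is two-condition only, and the single-pass SD
  caveat above applies to small scatters.
* Boundary localization inherits the ≈ w/2 edge bias of the window
  statistic; callers needing base-pair change-points should treat these
  boundaries as initialization, not truth.
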