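# stairstep

Broad chromatin domain calling and boundary detection from paired-end
ChIP-seq fragment intervals.

## The problem

Repressive chromatin marks such as H3K27me3 form broad domains — tens to
hundreds of kb — whose extent can differ between closely related cell
populations. The canonical case is a Hox cluster profiled in successive
parasegments: each more posterior population has lost the mark over a
larger proximal span of the locus, producing a nested "stairstep" of
covered/clear domains with sharp boundaries. Detecting those domains and
locating their boundaries requires statistics adapted to broad, flat
enrichment rather than sharp peaks, plus a way to compare domain density
between conditions genome-wide.

This package is for analysts with aligned, deduplicated paired-end ChIP
and input fragments (BED-like intervals) for one or more conditions, who
want reproducible region calls, per-condition covered/clear segmentation
of a locus, and a ranked list of regions whose chromatin density differs
between two conditions.

## The method

1. **Input normalization.** For every genomic position, with ChIP coverage
   *n*(x), input coverage *n*ᵢ(x), and genome totals *N*, *N*ᵢ:

   *n*ₙₒᵣₘ(x) = [(*n*(x)+1)/(*n*ᵢ(x)+1)] · (*N*ᵢ/*N*)

2. **Window enrichment.** Normalized coverage is summed in sliding windows
   (1 kb, step 50 bp). An empirical null is built by redrawing every ChIP
   tag at a uniform position on its chromosome (length preserved) and
   recomputing the same statistic against the true input, over several
   rounds. Window p-values use the add-one estimator
   p = (1 + #{null ≥ obs}) / (1 + #null); significant windows merge into
   enriched regions, and with replicates only the intersected extent
   survives.

3. **Differential density.** Enriched regions from all conditions are
   merged; regions over 50 kb are split into equal sub-regions; each
   region's density (total normalized coverage / length, replicate-
   averaged) for two conditions is scatter-fitted by ordinary least
   squares, and each region is scored Z = residual / residual SD. Extreme
   |Z| regions are the candidate differing regions.

4. **Segmentation.** Per-condition region calls over a locus become a
   covered/clear state matrix on the window grid; short state flickers are
   absorbed, and the surviving run transitions are the domain boundaries.
   A nesting check verifies that clear domains grow along the condition
   order.

5. **Synthetic validation.** A fragment simulator plants the stairstep
   geometry (nested clear spans of 92 / 137 / 173 kb in a 380 kb locus on
   a 2 Mb chromosome), with Poisson tag placement, truncated-normal
   fragment lengths, replicate noise, and a tunable fraction of anterior
   contamination, so the whole pipeline is testable end to end with no
   external data.

## Worked example

The numbered drivers under `analysis/` run the whole study at quarter
scale (about two minutes total):

```sh
Rscript analysis/01_simulate.R          # synthetic samples -> results/sim/
Rscript analysis/02_run_pipeline.R      # full pipeline     -> results/run/
Rscript analysis/03_boundary_report.R   # boundary accuracy
Rscript analysis/04_contamination_sweep.R
```

`03_boundary_report.R` prints (quarter scale, so planted clear extents are
23,000 / 34,250 / 43,250 bp):

```
    condition planted_clear_bp recovered_clear_bp extent_error_bp
PS4       PS4                0                  0               0
PS5       PS5            23000              22500            -500
PS6       PS6            34250              33750            -500
PS7       PS7            43250              42700            -550
boundary errors (bp): 500, 500, 550; MAE = 517 bp
```

Each condition's recovered clear extent is within one window width
(1 kb) of the planted value; the ~500 bp deficit is the expected edge
bias of 1 kb windows straddling a sharp boundary. The contamination sweep
shows mean normalized coverage over the PS5-analog clear interval rising
monotonically with the contamination fraction (0.62 → 0.97 from 0% to
20%) while the interval itself stays essentially free of enrichment calls
(≈ 2% of its length) — residual signal is read through, not called as a
domain.

In R, the same pipeline is three calls:

```r
library(stairstep)
spec <- bxc_stairstep_scenario(scale = 0.25, seed = 1)
dat  <- generate_tags(spec)
# ... positional_coverage / normalize_coverage / window_sums / build_null /
# call_windows / merge_windows / intersect_replicates per sample, then:
# state_matrix + call_boundaries over the locus. See ?stairstep.
```

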