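---
title: "Signal-to-noise bias in GeoMx DSP counts: QC, normalization and network methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal-to-noise bias in GeoMx DSP counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement model and its assumptions

GeoMx DSP counts are an indirect readout: each target gene is measured
by 3–5 probes, and a panel of negative-control (ERCC spike-in) probes
with no tissue target estimates the background signal. The pipeline in
this package rests on three assumptions:

1. probe counts for one target in one ROI scatter around a common
   target level, so their **geometric mean** is the target value;
2. the negative-probe counts in an ROI characterize the background of
   *all* probes in that ROI, so a per-ROI **limit of quantification**
   (LOQ) — the negative geometric mean raised by two geometric standard
   deviations — separates quantifiable signal from noise;
3. most genes are not differentially expressed between conditions, so
   group-level differences in the *shape* of the count distribution are
   technical, not biological.

Assumption 3 is the crux. When one group systematically shows higher
background and lower capture efficiency, its signal-to-noise ratio
(S/N = target value / LOQ) is depressed across the board. Scale-factor
normalizations (Q3, CPM, median-of-ratios) only multiply each ROI by a
constant; they align one quantile or one sum, not the distribution
shape, so the low-S/N group's background values end up inflated and the
log2 fold change becomes a monotone function of S/N. Rank-based methods
(gamma-fit correction, quantile) force distributional agreement and
remove most of this artifact.

## QC parameters

All defaults follow standard GeoMx practice; each is a field of
`qc_params()`:

| parameter | default | meaning |
|---|---|---|
| `low_count_threshold` | 5 counts | a probe count at or below this is "low" |
| `low_count_max_rois` | 2 ROIs | exclusion needs low counts in *strictly more* ROIs |
| `global_outlier_ratio` | 0.1 | minimum probe-to-target geomean ratio |
| `grubbs_alpha` | 0.05 | two-sided level of the per-(target, ROI) Grubbs test |
| `grubbs_roi_fraction` | 0.2 | exclusion needs flags in strictly more than this ROI fraction |
| `roi_spikein_min_geomean` | 10 counts | ROIs with lower negative geomean are dropped |
| `loq_sd_multiplier` | 2 | geometric SDs above the negative geomean |

Three rules are ambiguous in common usage and therefore selectable:

- **Low-count rule.** The default reads "excluded if ≤ 5 in more than
  2 ROIs" literally; `low_count_rule = "inverted"` keeps a probe only
  when it *exceeds* 5 in more than 2 ROIs.
- **LOQ scale.** The default is geometric
  (`LOQ = geomean × GSD²`), the reading consistent with log-scale
  background noise; `loq_mode = "arithmetic"` uses
  `geomean + 2·sd`.
- **Negative-probe exemption.** Negative probes are exempt from the
  low-count filter by default: they *measure* background, and removing
  the low ones would bias the LOQ upward.

The Grubbs test runs one pass per (target, ROI) — only the single most
extreme probe is tested, with critical value
`G = ((n−1)/√n)·√(t²/(n−2+t²))`, `t` the upper `α/(2n)` Student-t
quantile with `n−2` df. Iterative removal is not applied; with 3–5
probes per target a second outlier is not meaningfully testable.

Zeros are lifted to 1 before any log-space operation. Collapsed values
are therefore ≥ 1 and the log2 transform needs no pseudocount; values
below 1 can only arise after CPM rescaling, where they are floored at 1
with a recorded warning count.

## Normalization methods

- **Q3**: each ROI divided by its 75th percentile (linear interpolation
  between order statistics, R type 7) and rescaled by the geometric mean
  of all ROIs' quartiles. A pure within-column linear map.
- **CPM (modified)**: value / column sum × 10,000.
- **Median-of-ratios**: values rounded to integers; size factor = median
  ratio to the per-gene geometric mean over the zero-free reference set.
  The variance-stabilizing transform used downstream of such size
  factors elsewhere is *not* re-implemented; this package applies the
  shared log2 rule to the size-factor-scaled counts instead. The
  substitution is deliberate — the dispersion-trend machinery behind VST
  is out of proportion to its role here — and is stated wherever the
  method is reported.
- **Gamma-fit correction**: a two-parameter gamma is fitted to each
  ROI's values by maximum likelihood (profile-likelihood Newton
  iteration on the shape; the closed-form moment start makes it robust
  for values in the thousands). The reference distribution is the
  arithmetic mean of the fitted shapes and rates across ROIs (a pooled
  fit is available via `reference = "pooled"`); each value maps through
  `Q_ref(F_roi(x))`, a strictly increasing, rank-preserving transform.
  CDF values are clamped to `[1e-12, 1 − 1e-12]` so extreme points stay
  finite.
- **Quantile**: columns sorted, reference = rank-wise mean, values
  mapped back by rank. Ties within a column receive the mean of the
  reference values over the tied rank positions — the widely used
  convention. Note that with discrete input this tie rule means column
  multisets are only *nearly* identical; on continuous (tie-free) input
  they are exactly identical and all pairwise KS distances are exactly 0.

## Differential expression and benchmarking

Fold changes are median-based: `lfc = log2(median_A / median_B)` on the
natural scale (log2-stage matrices are de-logged first). Testing is a
two-sided Wilcoxon rank-sum per target — exact via the Wilcoxon null
distribution when both groups have ≤ 10 ROIs and no ties, otherwise the
normal approximation with tie and continuity corrections — followed by
Benjamini–Hochberg adjustment. The test is rank-based, so log2 and
natural-scale input give identical p-values.

The benchmark scores each method on (i) mean pairwise KS distance
between ROI distributions, (ii) MA-plot deviation (OLS of M on A,
reporting slope, R², and the slope's p-value; `A` pools both groups),
and (iii) |Spearman ρ| between per-target summed group-median S/N and
lfc. The composite ranking (mean rank across criteria, plus the
biological agreement criterion when a reference matrix is supplied) is
an artifact convention for presentation; the criteria themselves are the
result.

## The simulator: what it emulates and what it does not

`simulate_dataset()` draws, for probe `p` of target `g` in ROI `r`:

```
count ~ NegBin(mean = s_r · e_p · mu_g · 2^(delta_g · group_r) + b_r,
               dispersion = nb_dispersion)
```

with negative probes at `NegBin(b_r, dispersion)` and counts floored at
1. Defaults state a world resembling a cancer-transcriptome-atlas run:
1800 targets × 3–5 probes, 88 negative probes, 20 ROIs per group,
baseline expression log-normal (`meanlog = log 50`, `sdlog = 1.2`,
giving median S/N in the low single digits as real panels show), NB
dispersion 0.15, 50 DE targets at |log2 fc| = 1 with alternating sign,
and a 50-gene module whose mean scales with `1 + trait/λ` for a
Poisson(λ = 15) per-ROI T-cell count.

The group-differential S/N enters **jointly**: the higher-background
group (`background_mean_by_group = c(30, 10)`) also receives
proportionally lower capture efficiency (`s_r` centered at
`sqrt(b_other/b_own)`), reproducing the signature of high control-probe
counts with low target-probe counts in one group. When backgrounds are
equal the construction is exactly symmetric.

Choices a reader should know about:

- The NB noise model is a modeling convenience for overdispersed
  counts; the instrument's true noise distribution is uncharacterized,
  and dispersion is shared across probes.
- ROI background jitters log-normally (sdlog 0.2) around its group
  mean; per-probe efficiency is log-normal with mean 1 (sdlog 0.25).
  Both are unremarkable mid-range values for probe-level assays.
- Not emulated: spatial coordinates, segmentation, slide/batch
  replicate structure, probe cross-hybridization. A green test on
  simulated data establishes that the *algorithms* behave as specified
  under a known generative model — not that any particular real dataset
  is bias-free.
- A deliberate consequence of the additive background: in the
  high-background group, background-dominated targets lose rank
  information, not just distributional position. Quantile normalization
  restores the distribution but cannot restore corrupted ranks, so a
  residual S/N–fold-change association survives even under the best
  method (the acceptance suite measures it). On real data the same
  caveat applies: quantile normalization removes the distributional
  artifact, not the information loss below the LOQ.
- The trait-coupled module at these defaults has modest pairwise
  correlation (the shared multiplier varies by ~1/√λ against ~20%
  residual probe noise). It is detectable by direct gene–trait
  correlation but sits below the co-expression clustering detection
  limit; module *recovery* is exercised by the dedicated
  `simulate_module_matrix()` generator, whose latent-factor blocks have
  a stated within-module correlation (default 0.7).

## Network stage

Signed adjacency `((1 + cor)/2)^β` with β chosen as the smallest
candidate whose connectivity histogram fits a power law with signed
R² ≥ 0.8 (10 log-spaced bins, OLS on log10 frequency vs log10
connectivity; R² negated for a positive slope; `power_override`
short-circuits). Topological overlap uses the classic formula applied
to the signed adjacency; `1 − TOM` feeds average-linkage clustering.

The hybrid dynamic tree cut of the reference implementation is **not**
re-implemented. The simplified cut used here takes the tree at a fixed
fraction of its merge-height range — `deep_split` 0..4 maps to
0.95, 0.85, 0.75, 0.65, 0.55 (deeper split cuts lower) — then sends
clusters below `min_module_size` (default 30) to grey and iteratively
merges modules whose eigengenes correlate above 0.75. A quantile of the
merge heights was considered and rejected: the many near-zero
within-module joins dominate any quantile and shatter clean modules.
Because the cut is simplified, module *counts* on real data are not
comparable to the reference implementation; partition recovery on
planted structure is the supported contract.

Eigengenes are first principal components of the standardized module
expression, unit-norm, sign-oriented to correlate positively with the
module's mean standardized profile — a deterministic convention that
makes runs bit-reproducible. Module–trait p-values use the Student-t
transform `t = r√(n−2)/√(1−r²)`. Constant (zero-variance) gene profiles
are excluded from the network with a record; constant traits are
flagged degenerate rather than tested.

## Numerical and degenerate-input conventions

- Geometric mean/SD error on non-positive input; QC lifts raw zeros to
  1 first.
- Grubbs with zero within-cell spread flags nothing; targets with < 3
  probes are skipped.
- A single negative probe makes the geometric SD (hence LOQ) undefined
  and is an error, not a silent fallback.
- Fully tied rank-sum input (zero variance) reports p = 1.
- `sn_lfc_association()` on a constant vector reports ρ = 0 with a
  degenerate flag rather than NA.
- Exact-vs-approximate rank-sum switches at group size 10.

## The ROI spike-in filter and deliberately boundary-level backgrounds

The simulator's stated low-background group (mean 10) sits *at* the ROI
spike-in filter boundary: the geometric mean of NB(10) draws is ~9, so
the filter would remove most of that group and with it the contrast the
benchmark exists to measure. `run_qc()` and `pipeline_config()`
therefore expose `filter_rois`; the packaged acceptance and property
worlds run the probe cascade, collapse and LOQ with the ROI filter
disabled. On real data the filter should stay on — its purpose is to
drop failed ROIs, not to truncate a biological group.

## Known limitations

- Quantile normalization flattens genuine global differences along with
  technical ones and can compress subtle fold changes.
- The MA criterion is an OLS summary; curvature that averages out over
  expression strata is not captured.
- The network stage targets partition recovery, not parity with the
  reference WGCNA implementation.
- No covariate adjustment, paired testing or batch correction is
  provided; the DGE model is the two-group rank-sum test only.
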