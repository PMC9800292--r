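# geomxnorm

QC, normalization benchmarking and co-expression network analysis for
NanoString GeoMx Digital Spatial Profiler (DSP) probe-count data.

## The problem

GeoMx DSP measures each target gene with 3–5 hybridization probes per
region of interest (ROI), alongside negative-control (ERCC spike-in)
probes that estimate background. Background level and capture efficiency
can differ *systematically between experimental groups* (e.g. primary vs
recurrent tumor resections). The manufacturer's third-quartile (Q3)
normalization only rescales each ROI, so when one group has a lower
signal-to-noise ratio its background values are inflated relative to the
other group, and differential expression becomes a readout of
signal-to-noise rather than biology. This package is for analysts of
GeoMx count data who need to detect that bias, quantify it, and remove it
with rank-based normalization.

## What it computes

For each ROI `r`, from the negative-probe counts:

- geometric mean `g_r = exp(mean(log x))` and geometric SD
  `GSD_r = exp(sd(log x))`;
- limit of quantification `LOQ_r = g_r · GSD_r²` (two geometric standard
  deviations above the background geometric mean);
- per-target signal-to-noise `S/N(g, r) = value(g, r) / LOQ_r`, where
  `value` is the geometric mean of the target's surviving probes.

Probe QC follows the standard cascade: low-count filter (count ≤ 5 in
more than 2 ROIs), global outlier filter (probe geomean / target geomean
< 0.1), per-(target, ROI) Grubbs outlier filter (flagged in > 20% of
ROIs), ROI spike-in filter (negative geomean < 10), and the LOQ target
filter (kept iff above LOQ in ≥ 1 ROI).

Five normalizations are benchmarked — Q3, modified CPM, median-of-ratios
size factors, per-ROI gamma-fit correction, and quantile — against three
technical criteria: (i) pairwise two-sample Kolmogorov–Smirnov distances
between ROI distributions, (ii) the OLS fit of the MA plot
(`M = log2(median_A / median_B)` vs `A = log2(mean expression)`) against
the unbiased `M = 0` line, and (iii) Spearman's ρ between per-target
summed group-median S/N and the log2 fold change. An optional biological
criterion scores agreement of marker-gene Spearman correlation structure
with a reference (bulk RNA-seq) matrix. Differential expression uses
per-target Wilcoxon rank-sum tests with Benjamini–Hochberg correction. A
lightweight signed WGCNA-style stage (adjacency
`((1 + cor)/2)^β`, topological overlap, simplified tree cut, module
eigengenes, module–trait correlation with Student-t p-values) extracts
trait-associated gene modules.

A negative-binomial simulator generates probe-level datasets with known
ground truth — planted DE targets, a trait-correlated module, and the
group-differential background/efficiency structure — so every stage is
testable without external data.

## Worked example

```r
library(geomxnorm)

cfg <- pipeline_config(simulation = simulation_config(seed = 1),
                       filter_rois = FALSE, seed = 1)
res <- run_pipeline(cfg, "geomx_out")
print(res$qc)
print(res$benchmark)
```

which prints (seed 1):

```
GeoMx QC cascade
  probes: 7326 -> 7245 (low count) -> 7245 (global outlier) -> 7245 (Grubbs)
  ROIs: 40 -> 40 (spike-in geomean)
  targets: 1799 collapsed -> 1742 above LOQ

Normalization benchmark (best first):
   method ks_mean_d ma_r_squared sn_lfc_abs_rho mean_rank
 quantile   0.00071       0.0268          0.214      1.00
    gamma   0.03860       0.1023          0.441      2.00
       q3   0.15540       0.7169          0.951      3.67
      mor   0.10869       0.7296          0.952      4.00
      cpm   0.15575       0.7306          0.952      4.33
```

Reading: on data with a planted group-differential background, Q3-scaled
values leave the log2 fold changes almost entirely explained by
signal-to-noise (|ρ| ≈ 0.95, MA R² ≈ 0.72); quantile normalization
forces identical ROI distributions (KS ≈ 0) and collapses the MA trend
(R² ≈ 0.03), ranking best overall. The rank-based gamma-fit correction
sits in between; the scale-factor methods (Q3, CPM, median-of-ratios) do
not address the bias.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full pipeline from scratch on a freshly simulated
dataset — simulation, QC cascade, all five normalizations, the
benchmark ranking, Wilcoxon differential expression and the network
stage — printing the summaries above and writing the result JSON to
`--out`. The seed controls every source of randomness; identical seeds
reproduce identical outputs.

## Command line

A thin CLI over the same functions is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/geomx.R", package="geomxnorm"))')" \
    run --config pipeline.yaml --out geomx_out
```

with subcommands `simulate`, `qc`, `normalize`, `dge` and `run`.
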