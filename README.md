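# cumcnv — cumulative copy-number-variation profiles from methylation arrays

`cumcnv` turns methylation-array log2-ratio data into cohort-level
("cumulative") copy-number-variation profiles. It is aimed at anyone who
has a case series profiled on Illumina methylation arrays (450k, EPIC,
EPICv2, mouse) — or any other source of bin-level log2 ratios — and wants
to know *which* regions are gained or lost, *how strongly*, and *how
often* across the cohort, without stitching together half a dozen
single-sample tools.

## What it computes

The core of the package is a **multi-sample penalised least-squares
piecewise-constant fit with shared breakpoints** (combined segmentation,
CS). For one chromosome with bins *i = 1..n* and samples *s = 1..S* it
minimises, by exact dynamic programming,

    sum_s SSE_s / sigma_s^2  +  gamma * S * log(n) * K

where *K* is the number of breakpoints shared by all samples, *SSE_s* the
residual sum of squares of sample *s* about its per-segment means, and
*sigma_s* a robust (successive-difference MAD) estimate of the sample's
bin-level noise. Because every sample shares the same boundaries, segment
× sample matrices, frequency plots and downstream clustering come out
aligned by construction. On long chromosomes a high-pass-filter candidate
heuristic keeps the dynamic program fast; small inputs are always solved
exactly.

Around that core:

* control-based normalisation of probe intensities (scalar linear
  reference fit, or tangent projection onto the control span);
* genomic binning (50-kb windows merged to ≥ 15 probes, median per bin);
* a self-contained per-sample **circular binary segmentation** (SW mode)
  with permutation significance and optional inverse-variance weights;
* aberration calling in {−1, 0, +1} at a strict threshold θ (default
  0.2), noise-adjusted for CBS segments (θ_CBS = θ × noise_seg), with
  sub-2-bin segments filtered;
* chromosome-arm condensation (length-weighted means), similarity-ordered
  gain/loss matrices, and the four cumulative plot kinds (CS/SW ×
  intensity/frequency);
* a synthetic-cohort generator with known ground truth and a **Monte
  Carlo benchmark** for focal-aberration sensitivity.

## Worked example

Simulate a 20-sample cohort on two 300-bin chromosomes with a broad loss
(−0.5 on chr1p in 80 % of samples) and a focal gain (+1 over 10 bins of
chr2 in 40 %), then segment and call:

```r
library(cumcnv)

sim <- synth_bin_cohort(cohort_spec(
  n_samples = 20, chrom_bins = c("1" = 300, "2" = 300), noise_sd = 0.1,
  broad_events = list(
    list(chrom = "1", start_bin = 1,   end_bin = 150, strength = -0.5, fraction = 0.8),
    list(chrom = "2", start_bin = 101, end_bin = 110, strength = 1,    fraction = 0.4)
  ),
  seed = 7
))
bm <- sim$bin_matrix

cs <- segment_genome_cs(bm, pcf_config(gamma = 1))
cs$segments
#>   chrom start_bin end_bin n_bins
#> 1     1         1     150    150
#> 2     1       151     300    150
#> 3     2       301     400    100
#> 4     2       401     410     10
#> 5     2       411     600    190
```

Both injected events are recovered with exact boundaries: the chr1
half-chromosome loss (bins 1–150) and the 10-bin focal gain (global bins
401–410, i.e. chr2 bins 101–110). Calling at θ = 0.2 reports their
cohort frequencies:

```r
calls <- call_aberrations(cs, bm, calling_config(theta = 0.2, noise_adjust = FALSE))
data.frame(region = calls$regions$label, gain = calls$gain_freq, loss = calls$loss_freq)
#>                region gain loss
#>           1:1-7500000  0.0  0.8
#>    1:7500001-15000000  0.0  0.0
#>           2:1-5000000  0.0  0.0
#>     2:5000001-5500000  0.4  0.0
#>    2:5500001-15000000  0.0  0.0
```

The loss is seen in 80 % of samples and the focal gain in 40 % — exactly
the injected fractions. Arm-level condensation places the affected
samples' 1p at ≈ −0.5, and the sample-wise CBS mode agrees with the
combined fit at the arm level (median per-sample Pearson r = 1.00 on this
cohort; samples with no aberration have near-constant arm vectors, so
their correlations are uninformative):

```r
arms <- synth_arm_table(bm$bin_map)
round(arm_weighted_mean(cs, arms, bm)[, 1:5], 3)
#>     S001   S002   S003   S004   S005
#> 1p 0.015 -0.500 -0.502 -0.504  0.000
#> 1q 0.000 -0.015  0.001  0.006 -0.005
#> 2p 0.066  0.000  0.068  0.069 -0.002
#> 2q 0.000 -0.003  0.013 -0.009  0.015

sw <- segment_cohort_sw(bm, cbs_config(n_perm = 200, seed = 1))
median(mode_concordance(cs, sw, arms, bm))
#> [1] 1
```

Plot data (and figures) for the four cumulative plot kinds, SEG/BED/TSV
exports, and a one-call pipeline are available via `cs_intensity_data()`,
`cs_frequency_data()`, `sw_intensity_data()`, `sw_frequency_data()`,
`write_seg()` and `run_pipeline()`; a thin command-line wrapper lives at
`inst/scripts/cumcnv-run.R`. See the methods vignette
(`vignettes/cumulative-cnv-methods.Rmd`) for the models, parameter
meanings and design rationale.

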