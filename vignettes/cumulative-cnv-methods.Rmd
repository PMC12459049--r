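---
title: "Cumulative CNV profiles from methylation arrays: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cumulative CNV profiles from methylation arrays: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cumcnv)
```

## The problem

Copy-number variation (CNV) can be inferred from Illumina methylation
arrays because the summed methylated + unmethylated intensity of a probe
tracks local DNA quantity. Tumour cohorts are routinely profiled on these
arrays, and cohort-level ("cumulative") CNV summaries — how strong and how
frequent gains and losses are across a case series — are a standard way to
characterise an entity. The obstacle is that classical per-sample
segmentation gives every sample its own segment boundaries, which makes
cohort summaries awkward and slow.

`cumcnv` derives cumulative CNV profiles from bin-level log2 ratios in two
modes:

* **CS (combined segmentation)** — one multi-sample penalised
  least-squares piecewise-constant fit per chromosome, so all samples
  share identical breakpoints;
* **SW (sample-wise)** — circular binary segmentation (CBS) per sample,
  optionally weighted by inverse bin variance, with overlapping segments
  re-atomised afterwards.

Both modes feed a common calling, arm-condensation and plotting layer, and
a Monte Carlo benchmark measures focal-aberration sensitivity under known
ground truth.

## Preprocessing model

**Normalisation.** Two control-based modes convert non-negative probe
intensities $q$ to log2 ratios:

* *linear reference*: a single scale factor per query sample,
  $a = \sum q r / \sum r^2$ against the per-probe control median $r$,
  then $\log_2 q/(a r)$. A global scaling of the query is absorbed by the
  fit, which is the intended behaviour: only relative structure along the
  genome is meaningful.
* *tangent*: ordinary least-squares projection of the query vector onto
  the span of the control vectors, then $\log_2(q/\hat q)$ with the fit
  floored at $10^{-6}\times$ its median positive value so the ratio is
  always finite. Rank-deficient control sets are projected onto the span
  of their independent columns with a warning. The fit is unconstrained
  (not non-negative) least squares: it is deterministic and has a
  closed-form oracle, which the tests exploit.

Probes whose control reference is zero are dropped and counted. Both modes
are invariant to positive scaling of the query sample, and neither output
contains NaN or infinities — these are tested properties, not aspirations.

**Binning.** Each chromosome is tiled with 50-kb windows; windows are
accumulated left to right and a bin is emitted as soon as it holds at
least 15 probes (the usual granularity for 450k/EPIC-class arrays). A
trailing accumulation with fewer probes merges back into the previous bin,
so the probe floor holds whenever the chromosome itself holds enough
probes. The merge direction is strictly left-to-right because it is
deterministic and independent of the data values. Bins never cross
chromosome boundaries; they may cross centromeres (arm summaries later
split by arm). The bin value is the median probe log2 ratio; the
population variance of the member probes is kept as the weight denominator
for weighted CBS.

## Combined segmentation (CS)

For one chromosome with bins $i = 1..n$ and samples $s = 1..S$, the fit
minimises

$$\sum_s \frac{1}{\hat\sigma_s^2}\,\mathrm{SSE}_s(\text{segments})
  \;+\; P \cdot K,$$

where $K$ is the number of interior breakpoints shared by all samples,
$\mathrm{SSE}_s$ is the residual sum of squares of sample $s$ about its
per-segment means, and $\hat\sigma_s$ is the sample's bin-level noise,
estimated by the successive-difference MAD
$\mathrm{median}(|v_{i+1}-v_i|)/(0.6745\sqrt2)$ pooled within chromosomes
(robust to the piecewise-constant signal itself). A dynamic program with
$O(1)$ segment costs from prefix sums finds the exact global minimiser;
ties within $10^{-12}$ break toward fewer breakpoints.

**Penalty scaling.** The user-facing penalty is $\gamma$. With
`penalty_scale = "per_sample"` (the default) the effective per-breakpoint
penalty is

$$P = \gamma \, S \, \log n .$$

The $S$ factor makes $\gamma$ transferable across cohort sizes; the
$\log n$ factor is the BIC-flavoured correction needed because splitting
pure standardised noise at any *fixed* position already reduces the cost
by a $\chi^2_1$ per sample (mean $S$ in total), and the DP maximises over
$n$ candidate positions. A penalty proportional to $S$ alone therefore
sits at the noise floor and over-segments; with the $\log n$ factor,
$\gamma$ in the 0.5–5 range spans sensitive to conservative behaviour at
realistic cohort and chromosome sizes, which is what the Monte Carlo
benchmark verifies. `penalty_scale = "per_cohort"` applies the raw
$\gamma$ per breakpoint for direct control (and for hand-traceable
examples).

**Fast path.** Chromosomes with at most 400 bins are always solved
exactly. Above that, two high-pass moving-difference filters (half-widths
1 and 5 bins: sharp steps and low-amplitude steps) score every interior
boundary as $\sum_s |\bar v_\text{left} - \bar v_\text{right}|/\hat\sigma_s$;
boundaries that are local maxima of either score above a low threshold
(default 1) become the candidate set, and the DP runs restricted to it.
The restricted cost is an upper bound on the exact optimum by
construction; in the multi-sample regime the two agree in ≈ 98–100 % of
pure-noise trials at $\gamma = 1$ (tested). In the marginal single-sample
regime at $\gamma = 1$ the exact DP still places a few noise breakpoints
and the heuristic only bounds it; agreement is restored by $\gamma = 2$.

## Sample-wise segmentation (SW)

The CBS implementation is self-contained and deliberately simple: no
hybrid p-value approximation and no undo/prune passes. For an interval,
the arc $i..j$ maximising the two-sample statistic
$|\bar v_\text{arc} - \bar v_\text{rest}|/\mathrm{SE}_\text{pooled}$
(pooled variance floored at $10^{-12}$ so noiseless steps give a large
finite statistic) is assessed by permutation: the p-value is
$(1 + \#\{\text{perm max} \ge \text{obs}\})/(n_\text{perm}+1)$, and the
interval splits when $p \le \alpha$ (defaults $\alpha = 0.01$,
$n_\text{perm} = 1000$, minimum segment width 2 bins). The permutation
loop stops early once the exceedance count already forces $p > \alpha$,
which changes nothing about the decision but makes null intervals cheap.
Weights enter as inverse-variance multipliers
$w = 1/(\text{probe variance} + 10^{-8})$, normalised to mean 1 per sample
so weighted and unweighted segmentation coincide under equal variances.
All randomness flows from the configured seed; per-sample, per-chromosome
seeds are derived deterministically from it.

## Calling, arms, ordering

A segment (CS) or atomic interval (SW; the intervals between the union of
all samples' breakpoints) is called a gain (+1) or loss (−1) when its
per-sample mean strictly exceeds the effective threshold
$\pm\theta_\text{eff}$, else 0. The base threshold is $\theta = 0.2$.
Strict inequality is used so a mean of exactly −0.2 (or the common
borderline −0.193 seen in practice) is *not* a loss. Rows with fewer than
2 bins are removed from the aberration matrix entirely — single-bin
calls are the classic false-positive mode of noisy arrays.

For CBS-derived segments the threshold is additionally multiplied by a
per-segment noise factor
$\text{noise}_\text{seg} = \max\!\big(1,\; \mathrm{sd}(\text{residuals})
/ \text{reference}\big)$, where the reference is the cohort-wide median
of within-segment residual SDs. The floor at 1 means adjustment only ever
*raises* the threshold: its purpose is false-positive suppression, never
extra sensitivity. The combined fit does not use the adjustment (its
shared segments already pool evidence across samples).

Arm-level condensation takes, per sample and arm, the mean of segment
means weighted by the number of member bins falling in the arm (bins are
assigned to arms by midpoint). Arm calls use the same threshold rule
without the bin filter. Sample ordering for the exported matrix clusters
the $\{-1,0,1\}$ columns by Hamming distance with average linkage;
columns are pre-sorted by sample ID so ties resolve deterministically,
and an all-identical cohort keeps its input order.

## Plot data

The four cumulative plot kinds are built as plain layer tables on a
concatenated genome axis; rendering is a thin ggplot2 step, and all
testing targets the tables (pixel assertions are brittle and the plots
are fully data-determined):

* *CS intensity*: per-bin cross-sample means as a jittered point layer
  (horizontal jitter within the bin width, seeded) under per-segment
  cross-sample means of the per-sample segment means;
* *CS frequency*: gain frequency up, loss frequency down, per segment;
* *SW intensity*: one rectangle per sample-segment at its mean, each with
  opacity exactly $1/S$ so recurrent aberrations darken;
* *SW frequency*: the CS frequency construction on the atomic intervals.

Gene labels mark the bin holding the most of a gene's probes (ties to the
leftmost) and appear only when that bin's intensity satisfies
$|v| \ge 0.15$ (inclusive, per the conventional annotation rule).

## Synthetic cohorts and the Monte Carlo benchmark

The generator emulates bin-level log2-ratio cohorts: i.i.d. Gaussian bin
noise (default sd 0.1, a typical bin-level dispersion for good-quality
arrays and the value all acceptance bounds are stated under) plus
injected broad and focal events of known span, strength, and affected
samples. A probe-level variant draws shared lognormal baseline
intensities with multiplicative noise so that the full
normalise-bin-segment chain can be tested end to end. What the generator
does **not** emulate: probe-type chemistry, batch and FFPE effects,
tumour purity dilution, spatially correlated noise, and waviness. Passing
tests therefore demonstrate algorithmic correctness under the declared
noise model, not clinical performance on real arrays.

The benchmark draws, per iteration, a focal event — uniform location,
frequency from $\{0.2, 0.4, 0.6, 0.8, 1\}$, strength from
$\{0.5, 1, 1.5, 2\}$ — pads it by 3 bins per side to at least 7 bins
(focal drivers such as *SMARCB1* losses or *MYCN* amplifications typically
span 7–11 bins), injects it, segments, and scores the event as found only
when a segment reproduces the injected boundaries exactly (tolerance 0 by
default; configurable). The observed frequency is the fraction of samples
whose mean on the matched segment exceeds $\theta$; false positives are
called rows disjoint from the injected span, counted after the two-bin
filter. Affected-sample counts use `round(frequency × S)`.

**Problem sizes.** The shipped acceptance runs use 200 iterations of
60-sample × 2,000-bin cohorts (4 chromosomes × 500 bins) — sizes chosen
so the whole benchmark is comfortably reproducible on a laptop while
keeping every stratum populated; boundary-recovery checks use 100 seeded
trials at the weakest admissible event (strength 0.5, i.e. per-bin
$z = 5$). The DP-optimality oracle enumerates all $2^{n-1}$ breakpoint
sets on 200 random matrices with up to 12 bins and 4 samples.

## Numerical choices and degenerate inputs

* noise estimator floor $10^{-8}$; pooled-variance floor $10^{-12}$;
  weight epsilon $10^{-8}$; tangent fit floor $10^{-6}\times$ median.
* DP ties (within $10^{-12}$) break toward fewer breakpoints; CBS arc
  ties keep the first maximum in scan order (shortest arc, leftmost).
* Single-bin chromosomes segment trivially; single-bin segments get noise
  factor 1; empty chromosomes are skipped with a warning; zero-probe
  windows never form bins alone.
* BED input is 0-based half-open and converted to the internal 1-based
  inclusive convention on load; SEG export uses bp coordinates of the
  first/last bin of each segment.
* Mixed-array cohorts are harmonised by probe-ID intersection with
  coordinates from the first table. Model-based cross-array imputation is
  a different method and out of scope; for strongly divergent arrays,
  per-array analysis is advisable (the empty-intersection error says so).

## Known limitations

* The CBS stand-in is faithful but simplified; boundaries are not
  bit-compatible with DNAcopy/conumee.
* The linear-reference mode fits a single scalar; aberrations covering a
  large genome fraction pull the fit and shift the baseline (visible in
  the end-to-end tests as a small bias, ~the aberrant fraction).
* No GC correction, no allele-specific or integer copy numbers, no
  tumour-purity adjustment of thresholds.
* The calling threshold $\theta$ has no universally agreed value; 0.2 is
  the shipped default and all calls are threshold-relative.
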