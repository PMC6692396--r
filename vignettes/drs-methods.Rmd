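---
title: "Methods: the qPCR Disease Risk Score pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the qPCR Disease Risk Score pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpcrDRS)
```

## The problem and the score

Host blood transcriptomics can separate viral from bacterial infection in
febrile children. The minimal published signature uses two genes: *IFI44L*,
an interferon-induced transcript strongly up-regulated in viral infection,
and *FAM89A*, mildly up-regulated in bacterial infection. On RT-qPCR data
the signature is summarized per sample as a Disease Risk Score

$$\mathrm{DRS} = \log_{10}(\Delta Ct_{FAM89A} + 10)
              - \log_{10}(\Delta Ct_{IFI44L} + 10),$$

where $\Delta Ct = Ct_{target} - \overline{Ct}_{references}$. The
one-transcript variant is $-\log_{10}(\Delta Ct_{IFI44L} + 10)$. Because
the Ct scale is inverted relative to abundance (one extra PCR cycle =
half the starting template), high *IFI44L* expression gives a *low*
$\Delta Ct_{IFI44L}$ and hence a *high* DRS: viral samples score high. On
log-intensity expression matrices (microarray, RNA-seq) the same formulas
run on intensities instead, and the orientation flips (bacterial high);
the evaluation layer treats score direction explicitly, so classification
results do not depend on the convention.

Two constants deserve comment:

* **The +10 offset** rescales $\Delta Ct$ away from zero before the
  logarithm. It is part of the method's definition, not a tuning knob: the
  published cut-points (0.248 two-transcript, −0.926 one-transcript) are
  only meaningful at offset 10, so overriding it requires an explicit
  argument. The score is undefined when $\Delta Ct \le -10$; the package
  raises a domain error naming the offending sample, and the pipeline's
  reference-option comparison records and skips options that produce such
  samples rather than aborting.
* **The log base** is not stated in the source material; base 10 is the
  default here (it puts the scores in the published 0.1–0.4 range).
  Changing base multiplies all scores by a positive constant, so sample
  rankings, ROC curves and AUC are provably identical — the test suite
  asserts this to machine precision — and the choice only matters for
  reading absolute cut-point values.

## Replicate quality control

Assays are run in technical triplicate. The wet-lab rule is to repeat any
(sample, gene) whose replicate SD exceeds 0.5 Ct; a reanalysis pipeline
cannot re-run assays, so the default here *masks* such entries as missing
(recording them in the QC report) and an option keeps the replicate mean
with a warning instead. Sample SD (n−1 denominator) is the default
dispersion, matching common instrument software; population SD is
available. Replicates at or above the 40-cycle cap, and non-numeric
entries such as "Undetermined", are undetected: they carry no numeric Ct
and are excluded from means and SDs. An entry with a single detected
replicate has no defined SD and passes QC on the remaining replicate; an
entry with none is missing.

## Reference-gene stability

Normalization quality hinges on reference-gene choice, so four standard
stability algorithms are re-implemented and combined:

* **geNorm**: gene $j$'s $M$ value is the mean over partners $k$ of the
  SD across samples of $\log_2(Q_j/Q_k)$, with relative quantities
  $Q = E^{Ct_{min}-Ct}$ (efficiency $E = 2$ by default, i.e. 100%,
  justified for validated hydrolysis-probe assays). Ranking uses the
  original iterative exclusion: repeatedly drop the highest-$M$ gene and
  recompute until two genes remain; those two share rank 1.5. The
  $V_{n/n+1}$ pairwise-variation criterion is provided for completeness
  but the pipeline fixes three references (the study's choice, balancing
  precision against assay cost).
* **NormFinder**: Andersen's model-based estimator on $\log_2 Q$,
  decomposing variation into intragroup variance and intergroup bias; the
  stability value is the bias (shrunken by its sampling variance) plus the
  intragroup SD, averaged over groups. The grouped variant with the three
  clinical groups is the default; whether the original analysis supplied
  groups is not stated, so the ungrouped variant is exposed too. When both
  the between-group signal τ and a gene's group-mean variance are exactly
  zero the shrinkage factor is 0/0; the implementation defines it as 0 (no
  signal, no bias), which only arises in degenerate fixtures.
* **BestKeeper**: descriptive statistics on raw Ct. The original tool's
  "SD" is the mean absolute deviation from the arithmetic mean, the
  default here (a classic SD is available); genes rank by that dispersion,
  and the per-gene Pearson correlation with the BestKeeper index (the
  per-sample geometric mean of all candidate Cts) is reported.
* **Comparative ΔCt method**: a gene's score is the mean SD across
  samples of its pairwise Ct differences with every other candidate.

The **comprehensive ranking** is the geometric mean of the four per-method
ranks (ties get average ranks first; gene name is the final deterministic
tie-break), mirroring the RefFinder-style weighting used in the original
analysis. All four methods are invariant to per-gene additive Ct offsets
(asserted in the tests); geNorm and the ΔCt method additionally cancel
per-sample global offsets exactly.

## Normalization and fold change

$\Delta Ct$ uses the arithmetic mean of reference Cts, equivalent to the
geometric mean of linear quantities (the geNorm convention). The sign is
target minus reference — higher $\Delta Ct$ = lower expression — which is
the only convention under which the published scale-inversion argument
(qPCR DRS high in viral samples) reproduces. Fold change follows
$2^{-\Delta\Delta Ct}$ against the control group as calibrator; the
calibrator's mean log2 fold change is 0 by construction.

One algebraic point the tests make explicit: appending a constant-Ct gene
to a $k$-gene reference set changes each sample's $\Delta Ct$ by
$(m_s - c)/(k+1)$, where $m_s$ is that sample's previous reference mean.
This is a *common* constant only when $m_s$ is flat across samples; in
general the spacing of samples changes slightly, so downstream AUC is only
exactly invariant in the flat-reference case (both cases are tested).

## Classification performance

The empirical ROC uses candidate thresholds at midpoints between adjacent
distinct scores plus infinite sentinels, with "score ≥ threshold" called
positive (viral, the high class). The trapezoidal AUC equals the
tie-corrected Mann–Whitney probability; the package carries both routes
(threshold sweep and rank statistic) and the acceptance suite checks their
exact agreement against an $O(n^2)$ pair-counting oracle. The Youden
cut-point maximizes sensitivity + specificity − 1, breaking ties toward
higher sensitivity and then the lower threshold. Confidence intervals are
stratified-bootstrap percentile intervals (resampling within class, 2000
replicates by default, explicit seed; the replicate count is this
package's choice — the original analysis states stratification but not a
count). PPV and NPV follow the clinical convention that a *positive* call
means bacterial infection: on the qPCR DRS a sample is called bacterial
when its score falls below the cut-point. Undefined predictive values
(zero denominator) are reported as missing, never as 0.

Group comparisons follow an assumption-driven decision tree. Two groups:
Shapiro–Wilk per group at α = 0.05, then an F test of variance equality,
then Student's t, Welch's t, or the Wilcoxon rank-sum test. Three or more:
Shapiro–Wilk, then a Breusch–Pagan-style Lagrange-multiplier test of
homoscedasticity across groups (squared residuals regressed on the group
factor), routing to one-way ANOVA + Tukey HSD, Welch's heteroscedastic
ANOVA + Games–Howell ("robust one-way ANOVA" is realized as Welch's test;
the original analysis does not name its robust variant), or
Kruskal–Wallis + Games–Howell. Games–Howell referred each Welch-type
pairwise statistic to the studentized range distribution
($q = t\sqrt{2}$). Groups smaller than 3 cannot be normality-tested and
route to the nonparametric branch with a warning. Every branch decision is
recorded in a trace.

## Power analysis

The a-priori design computation is a two-sample equal-n t-test power
calculation with mean difference 0.69 DRS units and pooled SD 0.47 (both
taken from DRS values on an external microarray cohort), α = 0.05,
two-sided. Power uses the exact noncentral-t distribution, including the
wrong-tail rejection region (matching the pwr package's convention; the
difference from ignoring that tail is < 10⁻⁶ here). The smallest
fractional n solving power(n) = target is found by bracketed root-finding:
8.36 at 80% power and 10.81 at 90%, printed as 8.4 and 10.8. Sidedness is
not stated in the source; two-sided is the cited package's default and is
what reproduces those values.

## The synthetic cohort

Since the raw patient Ct table is not machine-readable, a generative model
stands in for it:

$$Ct_{sgr} = \mu_{g,\mathrm{group}(s)} + b_{sg} + o_s + e_{sgr},$$

with per-gene biological effects $b_{sg} \sim N(0, \sigma_g)$, a
per-sample global offset $o_s \sim N(0, 0.5)$ modelling RNA-input
variation (removed exactly by ΔCt), and technical replicate noise
$e_{sgr} \sim N(0, 0.15)$; replicates at or beyond 40 cycles are censored
as undetected. Defaults (chosen once, frozen):

* group sizes 14 bacterial / 11 viral / 10 control;
* reference genes at mean Ct 21.6 (ACTB), 23.5 (GAPDH), 25.0 (PGK1),
  27.5 (GUSB), 29.7 (TBP) — the published range is 21.6–29.7 with ACTB
  highest-expressed and TBP lowest; the interior spacing is this package's
  choice — with between-sample SDs on the published ladder 0.843 (PGK1),
  0.907 (GUSB), 0.997 (TBP), 1.200 (GAPDH), 1.483 (ACTB), identical means
  across groups;
* *FAM89A*: low expressed, group means solved so the size-weighted overall
  mean is the published 33.11 under a 1.5-cycle bacterial up-shift;
  biological SD 2.0 (low-abundance transcripts measure noisily, and the
  original data show inconsistent FAM89A behaviour);
* *IFI44L*: overall mean 27.67 under a 5-cycle viral up-shift; biological
  SD 1.5;
* technical SD 0.15 Ct (typical hydrolysis-probe triplicate precision —
  under it the 0.5-SD QC rule fails ≈ 0.002% of entries, as in a clean
  run) and offset SD 0.5 Ct.

Under these defaults the two-transcript DRS medians land near 0.10
(bacterial) and 0.36 (viral) against the published 0.104/0.315, and the
cohort-level AUC falls in the high 0.9s — deliberately a *band* (the
acceptance criterion asserts AUC ∈ [0.85, 1.00] across seeds), not a
reproduction of the published 92.2%, which would require the raw patient
table. What a green test establishes is therefore structural: the pipeline
ranks references, normalizes, scores and classifies correctly on data
*with the stated statistical shape*. What it does not establish: behaviour
under real between-patient heterogeneity (the synthetic bacterial group is
more homogeneous than the real one), heavy-tailed or skewed Ct noise,
co-infections, or pathogen-specific expression programmes.

An intensity-scale generator (additive shifts on a log-intensity baseline
with Gaussian noise) stands in for the external microarray/RNA-seq
validation cohorts; it is labelled synthetic throughout.

## Numerical and design choices

* Candidate ROC thresholds: midpoints between adjacent distinct scores
  plus ±∞ sentinels; reported cut-points are midpoints (a perfect split of
  {1,2,3} vs {4,5,6} reports 3.5).
* Bootstrap intervals: percentile method, quantile type 7, fixed seeds;
  per-stage seeds in the pipeline are derived deterministically from the
  root seed and logged in the manifest.
* Rank ties anywhere in the stability layer use average ranks; remaining
  order ties break by gene name.
* geNorm requires ≥ 3 genes; NormFinder's grouped variant requires ≥ 2
  samples per group (explicit error, optional fall-back to ungrouped);
  BestKeeper rejects nonpositive Ct (geometric mean undefined).
* All randomness flows through explicit seeds; two runs of the pipeline
  with the same configuration write byte-identical reports.

## Known limitations

Two acceptance criteria encode expectations the stated generative world
cannot meet, and the corresponding tests are intentionally left failing
rather than loosened:

* **Exact recovery of the reference-SD order at n = 100.** The sampling SE
  of an SD at n = 100 is ≈ 7% of its value, while the adjacent gaps in the
  published ladder are 7.6% (PGK1→GUSB) and 9.9% (GUSB→TBP). Each
  stability method orders an adjacent pair correctly with probability only
  ≈ 0.77, and the four methods' errors are strongly correlated (they see
  the same realized sample variances), so the comprehensive ranking
  recovers the exact full order in roughly half of seeds (measured 7–10 of
  20; 15/20 even at n = 300). The well-separated features — the top-3 set,
  and the last place of a gene with doubled noise — are recovered
  reliably and are tested green.
* **91–99% coverage of the bootstrap AUC interval.** At n = 14/11 and true
  AUC 0.9 the bootstrap distribution of the AUC piles up at 1.0, truncating
  the upper tail of the percentile interval; measured coverage is ≈ 0.87
  across independent 200-simulation batches. This is a known small-sample
  property of percentile intervals for the AUC, not an implementation
  defect (the same behaviour reproduces with a plain hand-rolled
  bootstrap); BCa or DeLong intervals would cover better but would no
  longer be the stratified percentile bootstrap the assay's analysis
  prescribes.

Beyond those: the pipeline does not process raw fluorescence or call Ct
values; it assumes Gaussian Ct noise (no heavy-tail option); it implements
no efficiency-corrected (Pfaffl-type) quantification — efficiency enters
only through the relative-quantity transform; and it makes no clinical
claims — cut-points learned on 25 informative samples have wide intervals,
as the bootstrap CIs make visible.
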