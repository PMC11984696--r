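---
title: "Estimating physiological age and decomposing lifespan-biomarker signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating physiological age and decomposing lifespan-biomarker signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(physage)
```

## The scientific problem

Isogenic populations reared in a common environment still show large
variability in lifespan. A useful way to think about this is that each
individual traverses a common physiological aging trajectory, but at its
own rate: at a fixed chronological age, a synchronized cohort contains a
spread of *physiological* ages. Lifespan-predictive biomarkers — here,
fluorescent reporters whose mid-life intensity correlates with remaining
lifespan — let us sort a population into predicted long- and short-lived
subpopulations and ask what distinguishes them transcriptionally.

`physage` implements that analysis end to end for bulk RNA-seq:

1. build an average aging trajectory from a time course of pooled samples;
2. estimate each sample's physiological (transcriptional) age by projecting
   it onto a principal curve fitted through the time-series samples in
   principal-component space;
3. decompose the gene-expression signature of biomarker-sorted samples into
   a component explained by physiological age and an *age-orthogonal*
   component that separates predicted long- from short-lived samples at
   matched physiological age.

A synthetic cohort generator with complete ground truth makes every stage
testable: planted aging rates, biomarker loadings, trajectory archetypes
and lifespans are all recoverable quantities.

## The statistical model

### Differential expression

Counts $Y_{gj}$ for gene $g$ in sample $j$ are modeled as negative binomial
with log link and a library-size offset $\log s_j$:

$$
\log \mu_{gj} = \beta_0 + \beta_{A1} x_j + \beta_{A2} x_j^2 +
\beta_{A3} x_j^3 + \beta_M m_j + \boldsymbol{\beta}_B^\top b_j + \log s_j,
\qquad \mathrm{Var}(Y_{gj}) = \mu_{gj} + \alpha_g \mu_{gj}^2 .
$$

Here $x_j$ is the sample's age (chronological or physiological, in days),
centered and scaled once and raised to powers 1–3; the cubic captures
non-monotone trends such as mid-life peaks. $m_j$ is the biomarker term:
in the *pooled* coding a single column with $+1$ for predicted long-lived,
$-1$ for predicted short-lived and $0$ for time-course samples; in the
*per-marker* coding one column per biomarker holding that marker's
fluorescence level ($+1$ high, $-1$ low). The level coding means each
per-marker coefficient keeps the marker's own sign convention, so the
pairwise correlation structure of the per-marker signatures reflects
whether two markers predict lifespan in the same or opposite direction.
$b_j$ are batch indicators (reference level dropped).

Coefficients are estimated by iteratively reweighted least squares with a
small ridge ($10^{-6}$) on the normal equations; standard errors come from
the inverse observed information, and significance from a two-sided
normal-reference Wald test with Benjamini–Hochberg adjustment per
coefficient across genes.

**Dispersion.** Per-gene dispersions use a method-of-moments estimate from
the design-residual variance of normalized counts,
$\hat\alpha_g = (\hat v_g - \bar\mu_g)/\bar\mu_g^2$, shrunk toward a
robustly fitted mean–dispersion trend $\alpha(\mu) = a_0/\mu + a_1$ by a
log-scale geometric mean (weight 0.5), clamped to $[10^{-8}, 10]$. This is
deliberately simpler than the Cox–Reid empirical-Bayes machinery of the
large DE frameworks: it reproduces the NB mean–variance contract that the
downstream inference needs, at the cost of some per-gene efficiency, and is
a documented source of count-level disagreement with analyses that use
those frameworks.

**Normalization and VST.** Size factors are median-of-ratios (rescaled to
geometric mean one). The variance-stabilizing transformation is the
closed-form NB stabilizer for the trend's asymptotic dispersion $a_1$,
$x = (2/\sqrt{a_1})\,\mathrm{asinh}\sqrt{a_1 y/s}$, which approaches the
Poisson stabilizer $2\sqrt{y/s}$ as $a_1 \to 0$. Batch effects are removed
from the VST matrix (only) by per-gene OLS on protected covariates plus
batch indicators, subtracting just the fitted batch component with the
first batch as reference; the GLM handles batch through its own term, so
correction and inference never double-count.

### Physiological age

PCA (gene-centered, unscaled) of the batch-corrected VST matrix gives
sample scores; by default the first three components are used, which is
where the aging trajectory is visually and numerically concentrated. A
principal curve is fitted through the *time-course* scores by the
Hastie–Stuetzle iteration: initialize the latent parameter by projection on
PC1, then alternate (i) per-coordinate cubic smoothing splines against the
parameter, (ii) dense resampling (512 vertices) and arc-length
reparameterization, (iii) re-projection of all points, until the mean
squared projection distance stabilizes (relative tolerance $10^{-6}$).

Every sample — time-course and sorted — is projected to the nearest point
of the curve. Physiological age is the arc-length position calibrated to
days: in the default *proportional* mode a linear map anchored at the mean
arc positions of the youngest and oldest chronological days; a *monotone*
mode (isotonic fit of day against per-day mean arc position, linearly
interpolated) is provided because "proportional to distance along the arc"
underdetermines the map when timepoints are not equally spaced along the
curve. The signed projection residual (sign taken along a configurable
reference axis, PC2 by default) is reported alongside, since samples that
leave the average trajectory do so systematically by predicted longevity.

### Trajectory clustering

Time-course VST values are averaged per timepoint, smoothed by a cubic
spline with 5 effective degrees of freedom, and z-standardized per gene so
that genes are compared by proportional, not absolute, change. Genes with
no age coefficient significant at FDR < 0.01 form **cluster 0** (no
correlation with time) and are excluded from clustering. The rest are
clustered by complete-linkage agglomeration on pairwise dynamic time
warping distances (Sakoe–Chiba band of radius 1 index = 1 day, squared
local cost, symmetric unit-weight steps, square root of the accumulated
cost), the tree is cut at $k = 5$, and centroids are computed by DTW
barycenter averaging initialized at the medoid (the DBA objective — the
sum of squared DTW distances to the centroid — is non-increasing by
construction and is checked in the tests). Because cluster numbers carry
meaning (1 up, 2 down, 3 early peak, 4 late peak, 5 mid trough), clusters
are relabeled by matching centroids to canonical shape templates on the
observed age grid, maximizing total Pearson correlation over label
assignments — a pure function of centroid shape, so labels are invariant
to gene order.

### Signature decomposition and enrichment

With physiological age in the design, a gene is *age-flagged* if any of
the three polynomial age terms is significant at FDR < $10^{-4}$ and
*marker-flagged* if the pooled biomarker term is. The four classes
(age-specific, marker-specific, intersection, neither) partition the
detected genes; marker-specific genes that additionally sit in cluster 0
— differentially expressed by predicted lifespan yet flat over time on
average — form the **age-orthogonal signature**. Treating "little to no
change over time" as cluster-0 membership is an interpretive choice; it is
the operational definition this package adopts and tests.

Enrichment uses a weighted Kolmogorov–Smirnov running-sum score over genes
ranked by $\mathrm{sign}(\beta)(-\log_{10} q)$, with a size-matched
gene-sampling null (the natural null for a ranked-list interface),
$\mathrm{NES} = ES/\overline{|ES_{\mathrm{null}}|}$ over same-sign nulls,
and permutation p-values floored at $1/(n_{\mathrm{perm}}+1)$ before the
signed $-\log_{10}$ display transform. Over-representation of a hit list
in an annotation set uses the upper-tail hypergeometric probability.

### Survival

Sorted subpopulations carry post-sorting survival records. Kaplan–Meier
curves use the product-limit estimator (deaths processed before censorings
tied on the same day), group comparison is the Mantel–Cox log-rank test,
and the headline effect size is the percent difference in median lifespan
(first time the curve reaches 0.5), predicted long- minus short-lived.

## What the synthetic cohort emulates

Individual $i$ has aging rate $r_i = e^{\epsilon_i}$,
$\epsilon_i \sim N(0, \sigma_r^2)$, so its physiological age at
chronological day $t$ is $r_i t$ — a linear time reparameterization, the
simplest model consistent with "a common trajectory traversed at different
rates". A latent factor $q_i \sim N(0,1)$, independent of $r_i$, carries
biology that separates individuals without moving them along the
trajectory. Each biomarker $m$ with sign $\sigma_m \in \{\pm 1\}$ reads

$$
b_{mi} = \sigma_m\!\left(-w_r \frac{r_i - 1}{\sigma_r} + w_q q_i\right)
 + N(0, \sigma_b^2),
$$

so markers share one underlying state (they are redundant predictors, as
observed for the real reporters) and lifespan
$L_i = L_0 e^{\eta_i}/r_i$, $\eta_i \sim N(0, \sigma_L^2)$, is
anti-correlated with the aging rate. Because the biomarker loads on both
$r_i$ and $q_i$, both an age-aligned and an age-orthogonal expression
signature exist in truth.

Gene trajectories follow six archetypes (flat; monotone up/down ramps over
days 2–12 normalized to $[0,1]$; Gaussian bumps centered at day 4 and day
9, width 1.8 days; a negated mid-trajectory bump at day 7), with per-gene
lognormal baselines, uniform log-fold amplitudes, and uniform NB
dispersions. Age-orthogonal genes are flat genes with a $\pm\gamma$
loading on $q_i$. Bulk samples pool individuals (default 30) *before* NB
sampling — one library per pooled population, matching pooled RNA-seq, not
per-worm sequencing. Sorted samples pool from the top or bottom decile
(nearest-rank on the realized cohort) of one marker's biomarker values at
the sort day; the survival table records the sorted deciles with a small
configurable random-censoring rate (default 5%).

Default study conditions: 500 individuals, $\sigma_r = 0.25$,
$w_r = w_q = 1$, $\sigma_b = 0.5$, four markers with signs
$(+1, +1, -1, -1)$, base lifespan 14 days with lognormal noise (SD 0.15),
3000 genes with archetype fractions (0.20, 0.30, 0.25, 0.10, 0.08, 0.07),
150 orthogonal genes at $\gamma = 0.8$, dispersions in $[0.01, 0.2]$, two
batches with log-scale SD 0.1, library-size SD 0.15, time course at days
2–12 with 3 replicates, sorting at day 5 with 3 replicates per group (the
replicate count per sorted group is not dictated by the experimental
design being emulated; 3 is a configurable default).

**What the generator does not emulate:** per-individual transcriptomes and
within-pool sampling noise beyond the NB library draw; count outliers and
heavy-tailed technical artifacts; genes whose temporal shape differs
between fast and slow agers (the linear reparameterization moves every
gene along the same curve); adaptive re-thresholding during sorting;
correlation structure among genes beyond what $r$ and $q$ induce. Passing
tests therefore demonstrate that the estimators recover the truth under
the stated model, not that real data satisfy that model.

## Numerical choices and edge cases

- **Age scaling.** Raw polynomials on centered, SD-scaled age keep the
  coefficients interpretable as the linear/quadratic/cubic age effects
  while restoring conditioning; orthogonal polynomials would decorrelate
  the columns but scramble interpretation.
- **Detection filter rounding.** "At least 5 counts in 75% of samples"
  uses the ceiling of $0.75\,n$ when $n$ is not divisible by 4.
- **Curve smoother.** The trajectory-clustering spline uses 5 df (a
  specified analysis choice); the principal-curve coordinate smoother uses
  4 df, chosen for stability with 11 timepoint groups. Tight curvature
  (e.g. a quarter circle) benefits from 5–6 df; the default favors the
  fairly gentle trajectories seen in aging time courses.
- **DTW details.** Squared local cost with a final square root and
  unit-weight symmetric steps; the band radius is interpreted in index
  units because the series are daily. Linkage and label assignment are
  deterministic; cluster-0 membership depends only on q-values.
- **Degenerate inputs.** Constant genes map to zero trajectories and are
  flagged; zero-variance design columns are pruned with a warning;
  confounded batch/protected designs error naming the collision; a
  dispersion trend that collapses to zero falls back to the Poisson
  stabilizer; GLM non-convergence is flagged per gene rather than fatal.
- **Ties.** Curve projection ties break toward the smaller arc position;
  ranking ties break by gene id; death/censor ties process deaths first.
- **Seeds.** All stochastic stages draw from named substreams of one
  master seed, so whole-pipeline runs are bit-reproducible.
- **Biomarker nonlinearity.** Because lifespan is $L_0/r$ while the
  biomarker is affine in $(r, q)$, the population Pearson correlation
  between biomarker and lifespan is bounded below 1 even without noise at
  the default $\sigma_r$; the rank correlation is 1 in the noise-free
  limit. Tests of the "biomarker predicts lifespan" contract therefore
  check Pearson correlation in the small-$\sigma_r$ linear regime and rank
  correlation at the default.

## Interfaces

The package is function-first, in the style of the established DE
packages: readers/writers for the tabular formats (counts TSV/CSV with
strict integer validation, metadata TSV, GMT gene sets, survival CSV,
ground-truth JSON), stage functions for each analysis step, and
`run_pipeline()`, which executes the stage sequence
simulate → filter → normalize → dge → cluster → physage → dge-phys →
decompose → enrich → survival against a YAML or list configuration,
writing per-stage artifacts and a JSON-lines log (parameters, seed,
package version) so any stage can be rerun from intermediates. These
functions, plus `scripts/acceptance.R`, are the command surface; no
separate shell binary is shipped.

## Problem sizes used in validation

The test-suite and acceptance runs use the default synthetic conditions
above (3000 genes, 57 samples), a 10-seed battery for the directional and
sign-structure checks, a 2000-gene null simulation for Wald calibration,
500 random gene sets (200 permutations each) for GSEA calibration, a
200-gene planted-archetype fixture at noise SD 0.1 for clustering
recovery, and exhaustive or 50-table oracle comparisons for the
statistical primitives. These sizes were chosen so a full validation run
completes in minutes on a single core while leaving the recovery margins
wide.

## Known limitations

- Physiological age is identified only up to the calibration map; between
  anchor days it is as linear in arc length as the trajectory itself is.
- The MoM/trend dispersion estimator is less efficient than
  empirical-Bayes shrinkage at small replicate counts; Wald tests run
  slightly liberal (the null simulation sits near 5–6% at nominal 5%).
- DTW clustering at $k = 5$ on noisy data merges shape families whose
  standardized trajectories are close (e.g. early peaks with monotone
  declines); the cluster-0 rule, not exact cluster counts, is the stable
  surface.
- The GSEA null samples genes, not phenotypes, and therefore tests ranked
  position, not between-sample exchangeability.
- Survival groups sorted by different markers share individuals in the
  synthetic truth (each marker's deciles are drawn from one cohort),
  unlike the separately sorted real populations; within-marker comparisons
  are unaffected.
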