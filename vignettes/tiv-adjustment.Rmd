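---
title: "Evaluating head-size adjustment methods with matched synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating head-size adjustment methods with matched synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Brain-morphometry measures scale with head size. Because total intracranial
volume (TIV) differs substantially between females and males (roughly
190,000 mm^3 between the sex means, against within-sex standard deviations
near 110,000 mm^3), any sex comparison of a regional volume, surface area or
deformation value is confounded by TIV unless it is adjusted for — and the
adjustment itself can distort the estimates it is meant to protect.
`allomatch` implements a framework for quantifying that distortion:

1. construct a *gold standard* — male–female pairs exactly matched on age
   and TIV, in which head size cannot drive a sex difference by design;
2. apply the common correction methods to an unmatched sample;
3. fit, per measurement unit, the standardized trajectory model
   `MOI ~ 1 + age + sex + age:sex` (the covariate variant adds `+ TIV`);
4. compare the resulting standardized estimates against the gold standard
   (correlation, regression slope, paired tests), and map the residual bias
   of each method, including its spatial association with allometry.

Real population-imaging data of the required size is access-restricted, so
the package ships a synthetic-cohort generator that reproduces the
statistical structure those analyses rely on, with known ground truth.

## The adjustment methods

For a measure of interest $MOI$ and a global variable $g$ (TIV by default,
or TSA/MCT/TCV/an alternative TIV source):

* **proportions**: $MOI_{adj} = MOI / g$ — assumes strict proportionality
  ($\beta = 1$);
* **power-corrected proportions (PCP)**: $MOI_{adj} = MOI / g^{b}$, with
  $b$ the OLS slope of $\log MOI$ on $\log g$;
* **residuals**: $MOI_{adj} = MOI - b\,(g - \bar g)$, with $b$ the OLS
  slope of $MOI$ on $g$ and $\bar g$ the fitting-sample mean;
* **covariate**: no value transform; $g$ (z-scored) enters the trajectory
  model as a regressor.

Slopes and means are always estimated on the pooled two-sex fitting sample
(by default the analysis subsample itself; per-group normalization is known
to bias sex comparisons, and which sample to fit on is switchable via
`fitting_sample`). Continuous predictors are z-scored within the analysis
sample; the outcome is z-scored within the analysis sample *after* the
correction; sex stays an unscaled 0/1 indicator with female as reference —
so the sex coefficient is a group contrast in outcome-SD units, and its
scale is not comparable to a z-scored predictor's. The interaction is the
product of z-scored age and the indicator, not re-standardized.

## The generator

`simulate_cohort()` draws, per sex, Gaussian TIV truncated at zero
(defaults: F mean 1,336,544.0, SD 103,196.89; M mean 1,525,386.9, SD
119,264.92 mm^3) and integer ages in months, uniform over 45–82 years and
independent of sex — so confounding control is exercised by the sampling
stage, not baked into the generator. A switch
(`age_sex_offset_months`) adds the ~1-year male age offset seen in real
cohorts when distributional realism matters more than orthogonality.

`simulate_measures()` generates unit $j$ for participant $i$ as

$$ v_{ij} = \alpha_j\, TIV_i^{\beta_j}\,
   (1 + slope_j\,\tilde a_i)\, e^{s_j [sex_i = M]}\; \epsilon_{ij}, $$

with $\tilde a_i$ age centered at the range midpoint in decades and
$\epsilon$ lognormal with unit mean. Choices and defaults:

* **Allometric exponents** $\beta_j \sim U(0.6, 1.1)$. The empirical
  distribution of regional exponents is not firmly established; this range
  covers strongly hypoallometric subcortical structures through mildly
  hyperallometric cortical tissue and is flagged as a modeling choice.
* **Scale constants.** `alpha_range` is parameterized as the expected unit
  size at the reference TIV (`tiv_ref`, 1.43e6 mm^3), i.e.
  $\alpha_j = size_j / tiv\_ref^{\beta_j}$, drawn log-uniformly between
  1,000 and 30,000 mm^3. A literal uniform $\alpha$ combined with a uniform
  $\beta$ would swing unit sizes over several orders of magnitude; since
  every analysis standardizes the outcome, this choice affects presentation
  only.
* **Noise** is multiplicative lognormal (`noise_cv`, default 0.15),
  keeping measures positive and making the PCP log-log fit exactly
  log-linear. 15% residual variability is typical of regional volumes once
  global scaling is accounted for (segmentation noise plus true individual
  differences).
* **Age decline**: fractional change per decade, $U(-0.04, -0.01)$ —
  1–4% volume loss per decade over the sampled age window.
* **True sex effects** $s_j$ have mean `sex_effect_mean` (0), independent
  spread `sex_effect_sd` (0), and a linear coupling
  `sex_effect_beta_coupling` to the centered exponent (0). With all three
  at zero, males and females differ only through TIV.
* **Metric variants**: `surface_area` behaves like volume in mm^2;
  `cortical_thickness` replaces every $\beta_j$ with the weak exponent
  `ct_beta` (0.1); `dbm` multiplies the volume value by $tiv\_ref / TIV$,
  emulating measures computed after linear normalization to a template —
  which flips the sign of TIV-driven sex differences in hypoallometric
  units, since the effective exponent becomes $\beta_j - 1$.
* The true per-unit parameters are returned with the matrix
  (`measure_truth()`): the framework's whole point is comparing estimates
  against a known truth, which no real dataset provides. A `truth`
  argument accepts caller-built parameter tables, e.g. spatially coherent
  fields on a mesh.

One RNG stream is derived deterministically per (seed, stage), so identical
configurations reproduce bit-identical tables regardless of which stages
run in between.

## The headline scenario

`headline_config()` freezes the conditions used for the method-ranking and
bias-allometry demonstrations: 42,000 participants per sex, 60 volume
units, $\beta \in [0.6, 1.1]$, `noise_cv` 0.15, and true sex effects
$s_j = -0.6\,(\beta_j - \bar\beta) + 0.04\,z_j$. Two considerations fix
the sex-effect structure:

* Matched-sample analyses of large cohorts find residual sex effects that
  are subtle, bidirectional and centered near zero; the scenario keeps the
  mean at zero.
* The regions most consistently reported male-larger beyond TIV
  (amygdala, putamen, hypothalamus, cerebellar structures) are
  hypoallometric, while hyperallometric cortical units show the reverse
  tendency — a negative coupling between $s_j$ and $\beta_j$. Under purely
  independent zero-mean effects, the residual bias of any method that
  removes TIV cleanly is proportional to $s_j$ alone and is therefore
  uncorrelated with the allometry map in expectation; the observed
  positive bias–allometry association requires effects that co-vary with
  scaling, and the coupled scenario reproduces it mechanistically.

The cohort size is set by the matcher's yield: at the 0.02% tolerance the
greedy matcher pairs roughly 0.01% of a 5,000-per-sex cohort but ~5% of a
42,000-per-sex cohort (the yield grows about quadratically in density),
giving the 2,000 pairs per analysis sample that the comparisons use. All
four subsamples are drawn at the same size, so they share one statistical
power.

## Matching

The matcher follows a first-fit scan: split by sex, randomize both orders,
and walk the males, claiming for each the first female (in randomized
order) within the relative tolerance on every matching variable.
Denominators are the male's values (females are found *for* males).
Tolerance 0.0002 applied to age in months admits only females with the
same integer month of age; whether the age criterion should instead be an
absolute cap is not specified anywhere authoritative, so relative-on-months
is used and documented. The scan is greedy without backtracking — an
order-dependent (seeded) process, deliberately not an optimal bipartite
matching; a brute-force matching oracle in the test suite bounds it from
above. The `extreme` design removes all matched members and resamples with
largest-remainder apportionment over the full-cohort age deciles,
preserving the age distribution while exaggerating the TIV gap.

Matching at this tolerance consumes the overlap of the two TIV
distributions: high-TIV females and low-TIV males. The matched sample is
therefore *not* representative of either sex's tails — its per-sex TIV SD
shrinks — which is the known cost of the design.

## Comparison, bias and spin test

`compare_estimates()` reports, per model term, Pearson r, the OLS slope of
test on reference (the reverse direction is available via a flag; an ideal
method has r near 1 *and* slope near 1 — high correlation with a shrunken
slope means systematic underestimation), a paired t-test and paired
Cohen's d (`mean(diff)/sd(diff)`), with Benjamini–Hochberg correction
applied across the terms of one report (the FDR family is a reporting
choice). Identical vectors return t = 0, p = 1 rather than NaN.

`bias_map()` measures each unit's signed orthogonal distance
$(test - ref)/\sqrt2$ from the identity line; positive bias is
undercorrection toward the male direction. `spin_test()` builds the
spatial null by uniformly rotating unit centroids on the sphere (QR-based
uniform rotations; the mirrored rotation is applied to the contralateral
hemisphere), reassigning each unit its nearest rotated neighbor, and
recomputing the correlation; the empirical p is
$(\#\{null \ge obs\} + 1)/(n_{perm}+1)$ — one-sided as the "exceeding"
rule reads, with the +1 guard against p = 0; a two-sided variant is a
flag. Unit centroids for synthetic maps come from a Fibonacci lattice
(`fibonacci_coordinates()`), since no real parcellation ships with the
package.

## Surface smoothing

`build_icosphere()` provides a watertight triangulated sphere
($10\cdot4^n+2$ vertices); `smooth_vertex_data()` applies a geodesic
Gaussian kernel with $\sigma = FWHM/(2\sqrt{2\ln 2})$, using graph-geodesic
distances along mesh edges (igraph shortest paths) scaled to mm by
`mesh_scale` (default sphere radius 100 mm, the order of a hemisphere).
Graph-geodesic distance overestimates true geodesic distance by at most a
few percent at icosphere regularity, which a renormalized kernel absorbs.
Weights are truncated at $3\sigma$ and renormalized (so constants are fixed
points exactly); missing values drop out of both sums; FWHM 0 is the
identity. On the subdivision-3 sphere the inter-vertex spacing is ~13 mm,
so 5 and 10 mm kernels truncate to the identity — smoothing effects appear
from 15 mm upward, matching the coarse mesh's resolution.

In the vertexwise demonstration the synthetic allometry and sex-effect
fields are generated with an 80 mm coherence scale, well beyond the largest
25 mm kernel. That is the regime in which the observed
"estimates-spread-grows-with-smoothing" behavior holds: smoothing removes
iid vertex noise from the outcome while leaving the effect fields nearly
intact, so the standardized estimates inflate. If the signal's coherence
scale were comparable to the kernel, heavy smoothing would begin to erode
the spread again — a caveat worth remembering when interpreting heavily
smoothed maps.

## What passing tests do and do not show

The generator emulates: sex-specific Gaussian TIV, power-law allometric
scaling with multiplicative noise, linear age decline, weak-TIV-coupled
thickness, template-scaled DBM, MCAR missingness, and (optionally)
allometry-coupled residual sex effects. It does not emulate: non-Gaussian
TIV tails, nonlinear or interaction-bearing age trajectories, spatially
correlated noise, scanner/site effects, segmentation failures correlated
with anatomy, or measurement error in TIV itself. Conclusions the test
suite supports are therefore about the *methods' behavior under the stated
generative assumptions* — notably that the covariate method tracks the
matched gold standard best while proportions can reverse sex-estimate
signs and PCP/residuals under-estimate with an allometry-patterned bias —
not about any particular real cohort.

Problem sizes used by the shipped analyses: 5,000/sex for the matching
validity checks, 25,000/sex for gold-standard centering, 42,000/sex (two
seeds, 2,000 pairs analyzed) for the method ranking, 12,000/sex on a
642-vertex sphere for the smoothing analyses, 100 units × 500 permutations
× 200 repetitions for spin calibration.

## Numerical choices and degenerate inputs

* Per-unit OLS uses one QR decomposition shared across units when the
  matrix is complete, with per-unit refits on complete cases otherwise.
* Zero-variance outcome units are flagged and skipped, never imputed;
  units with more than 20% missing participants are excluded before
  modeling (`filter_units()`).
* Adjusted R² follows the `summary.lm` convention
  ($1-(1-R^2)(n-1)/(n-p-1)$ with $p$ non-intercept predictors).
* BH-FDR delegates to `stats::p.adjust`; the testsuite checks it against a
  hand-written step-up computation.
* TIV draws are truncated at zero by resampling (negligible mass at the
  default parameters, but the positivity invariant holds exactly).
* `fit_power_exponent` refuses non-positive values naming the offending
  indices, since the log-log model is undefined there.

## Limitations

* The greedy matcher's yield collapses for small cohorts at the 0.02%
  tolerance; analyses needing a large gold standard must simulate large
  cohorts (the pipeline errors with the measured yield if asked for more
  pairs than exist).
* The spin test assumes unit centroids live on a sphere; it is not a
  variogram-matched null and inherits the usual mild miscalibration of
  rotation nulls for maps whose autocorrelation is anisotropic.
* The covariate method's regression slope against the gold standard sits
  slightly below 1 even in ideal conditions, because the unmatched sample's
  outcome variance contains between-sex TIV spread that the matched
  sample's does not — a z-scoring artifact of the design itself, visible
  in the shipped demonstrations.
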