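---
title: "Methods: distance decay, matrix regression and functional profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distance decay, matrix regression and functional profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxadecay)
```

`taxadecay` tests two complementary hypotheses about soil microbial
communities sampled across a large spatial gradient: that community
*composition* is biogeographically structured (similarity decays with
distance — endemism), and that community *function*, proxied by
functional gene array intensities, may nonetheless be spatially invariant
(functional redundancy). This vignette documents the models, the tunable
parameters, the numerical choices, and what the synthetic test bed does
and does not establish.

## The distance-decay model

For two samples with OTU count vectors $u, v$, Bray-Curtis dissimilarity
is $BC(u,v) = \sum_i |u_i - v_i| / \sum_i (u_i + v_i) \in [0,1]$, and
similarity is $S = 1 - BC$. The turnover model is the power law
$S = c\, d^{-2z}$ in geographic distance $d$, so that

$$\ln S = \ln c - 2z \ln d,$$

and `fit_distance_decay()` estimates the OLS slope $b$ of $\ln S$ on
$\ln d$ and reports $z = -b/2$. Conventions, all documented because the
literature varies:

- **Natural logarithms** on both axes. The slope of a log-log fit is
  base-invariant, hence so is $z$; only the intercept changes with base.
- **Similarity, not dissimilarity**, is regressed; the Bray-Curtis matrix
  is converted via $1 - BC$ when its kind tag says so.
- **Unusable pairs** ($S \le 0$, where the log is undefined, or $d = 0$)
  are excluded and counted in `n_dropped` rather than offset by a
  pseudo-value: any pseudo-constant would be arbitrary and would bias the
  slope, while the count keeps the exclusion transparent.
- Distances are **haversine great-circle kilometres** on a sphere of
  radius 6371.0 km. At a span of ~17° of latitude the datum choice is
  immaterial, and a spherical formula is reproducible from coordinates
  alone. Plot-to-plot (not site-centroid) distances are the default;
  centroid analyses can be had by aggregating the frame first.

### Bootstrap significance

`bootstrap_decay_test()` resamples the *pair list* with replacement
`n_boot` times (default 9,999), refits the slope each time, and applies a
one-sample t test of the bootstrap slope distribution against zero,
$t = \bar b / (s_b / \sqrt{B})$, with $p$ from $t_{B-1}$ (two-sided).
Two properties of this test form deserve emphasis:

- Because the denominator is the bootstrap standard *error* of the mean,
  $|t|$ grows as $\sqrt{B}$ on identical data. The test is therefore best
  read as "is the slope's sign unambiguous at this B", and the package
  also reports the scale-free ratio $\bar b / s_b$, which is
  B-invariant and whose $|{\cdot}| > 1.96$ rejection rate is calibrated
  near 5% under the null (checked by simulation in the test suite).
- Pair-level resampling treats the $n(n-1)/2$ pairs as exchangeable,
  ignoring that pairs sharing a sample are dependent (pseudo-replication).
  This is the convention that produces the very large |t| values familiar
  from the literature at B ≈ 10⁴; a more conservative sample-level
  bootstrap (resampling rows of both matrices) is available via
  `unit = "sample"`.

If every bootstrap slope is identical (noiseless data), the test is
degenerate: it is flagged, $t$ is reported as signed infinity and $p$ as
$1/(B+1)$ rather than 0.

## Regression on distance matrices

`mrm()` regresses the vectorised lower triangle of a response matrix on
predictor triangles by OLS. The vectorisation is row-major over pairs
$i<j$ and is the single fixed ordering used everywhere (`dist_pairs()`),
so matrices and pair lists are interconvertible without ambiguity.

Inference is by Mantel-style permutation: rows and columns of the
*response* matrix are permuted jointly, the triangle re-vectorised, and
the model refit; permuting the response (rather than predictors or
residuals) is the canonical MRM scheme. $p$-values are exceedance counts
with the identity permutation included,
$p = (\#\{stat^* \ge stat\} + 1)/(B + 1)$, so the smallest attainable
$p$ is $1/(B+1)$; coefficient tests are two-sided on $|\hat\beta|$ by
default. Predictor scaling changes coefficients but not $p$-values
(permutation distributions rescale with them).

Scalar covariates — elevation, plant Shannon diversity, PCA scores of the
soil-chemistry and climate blocks, function PC scores — enter as pairwise
absolute-difference matrices $|x_i - x_j|$ (`scalar_difference_matrix()`),
the only construction that makes a per-sample scalar commensurable with a
pairwise dissimilarity response. `single_matrix_regression()` adds the
one-predictor F statistic $F = (n-2)R^2/(1-R^2)$ over the $n$ pairs.
Collinear predictors are rejected up front with the offending pair named.

The number of permutations defaults to 9,999. The permutation null for
the R² test holds its size: the suite checks the empirical type-I error
at $\alpha = 0.05$ over 1,000 null data sets (15 samples, B = 199) and
requires it to fall in [0.03, 0.07].

## Ordination

**PCA** (`ord_pca()`) is a centred SVD; unit-variance scaling is on by
default because environmental variables mix units (pH against
millimetres of precipitation). The log-transform rule is: $\ln x$ when
all values are strictly positive, $\ln(x+1)$ when zeros are present,
error on negatives — recorded explicitly because "log-transformed" alone
underdetermines the treatment of zeros. Constant columns under
standardisation are an error naming the column.

**CA** (`ord_ca()`) decomposes the chi-square standardised residuals
$S_{ij} = (P_{ij} - r_i c_j)/\sqrt{r_i c_j}$ by SVD; eigenvalues are
squared singular values and sample scores are row principal coordinates.
A 2×2 diagonal table has first eigenvalue exactly 1 (perfect
association); an independence table (outer product of margins) has all
eigenvalues 0. The test suite verifies agreement with a dense
eigendecomposition oracle to 1e-8 and with `vegan::cca()`.

**DCA** (`ord_dca()`) re-extracts each axis after the first by reciprocal
averaging, detrending the sample scores against every prior axis at each
iteration by Hill's method of segments: order samples by the prior axis,
cut them into `n_segments` (default 26) equal-count segments, subtract
segment means. Iteration stops when scores change by less than `tol`
(1e-10) or after `max_iter` (30) passes. Deliberately **no nonlinear
rescaling** of axis units is applied: downstream use is the score
configuration (cluster structure), which rescaling stretches but does not
reorder. This is a documented deviation from full DECORANA; axis-1
scores and ordering are identical to CA by construction, and the suite
requires the detrending to remove at least 80% of the arch (quadratic
coefficient of axis 2 on axis 1) on a simulated one-dimensional gradient.
With two samples only one axis exists; missing axes are flagged
degenerate rather than silently filled.

## OTU table preprocessing

- **Singletons** are OTUs with *global* total 1 across all samples — the
  pooled-table convention that matches singleton removal performed after
  OTU building — and are removed before anything else. The default order
  is singleton removal, then rarefaction.
- **Rarefaction** (`rarefy_counts()`) is a single seeded
  without-replacement draw of exactly `depth` reads (default 20,000) per
  sample; samples below depth are dropped and named. A single draw (not
  an average over draws) is the default because downstream dissimilarity
  should be computed on one realisable data set; the hypergeometric draw
  preserves OTU proportions in expectation (verified over 500 seeded
  draws in the suite).
- **Shannon-Weaver** diversity is in nats; at OTU-scale richness this is
  the only base for which values land in the familiar 6–8.5 range.

## The functional gene pipeline

`function_profile_pipeline()` fixes the order: detection filter →
mean-total normalisation → category sums (→ optional $\ln(x+1)$). The
order matters — normalising before filtering would let unreliable spots
distort the sample totals — and the suite asserts the two orders differ.

- **Detection filter.** Undetected spots are *missing*, never zero; the
  filter counts detections (positive, non-missing) per probe within each
  site's sample group and masks the probe *in that site* when detections
  fall below `min_detected` of `group_size` (default 6 of 10). A site
  with a different sample count gets the proportionally rescaled
  threshold $\lceil 6/10 \cdot n \rceil$ with a warning; the workflow
  wrappers infer the modal site size so the 6-in-10 proportion carries
  over to other designs. Probes with no detection left anywhere are
  dropped.
- **Normalisation.** "Divide by the sample's total, multiply by the mean
  total": $x'_{sj} = x_{sj} / T_s \cdot \bar T$. This is the reading of
  mean-total normalisation that both removes per-sample scaling
  artefacts and preserves intensity units; afterwards every sample total
  equals the pre-normalisation mean total exactly (to 1e-9, asserted on
  a hand-worked fixture). Missing spots contribute zero to totals and
  stay missing.
- **Category sums.** Per sample, per registered category (18 C/N/P
  cycling gene families), the sum of detected intensities; unregistered
  probes are excluded and reported, empty categories are kept as explicit
  zeros with a warning, and per-category probe counts are attached as
  provenance. The filter is applied at probe level; aggregating probes
  to genes first is a caller-side transformation of the signal table.

## The synthetic test bed

The generators emulate the statistical structure the analyses assume, at
the study's design scale (24 sites × 10 plots from ~23°N to ~40°N at
108–112°E), and are pure functions of their seed:

- `simulate_pairwise_decay()` draws similarities directly from
  $S = c_0 d^{-2z}$ with optional lognormal noise, truncated to (0, 1] —
  the *exact* ground truth against which the estimator must be
  error-free without noise and unbiased with it.
- `simulate_community()` gives each OTU a Gaussian niche along latitude;
  `turnover_rate` scales niche narrowness, and per-phylum multipliers
  make realised turnover differ by phylum in a known order. Counts are
  multinomial at depth 25,000, so a 20,000-read rarefaction retains all
  samples. Because count-level data cannot hit an arbitrary target z
  exactly, decay ground truth is controlled twice: exactly at the
  similarity level (for estimator tests) and mechanistically at the
  count level (where only ordering and monotonicity are asserted). The
  default `turnover_rate = 2` was fixed once so that the realised
  all-sequence exponent of the full design is of order 0.1, the
  magnitude reported for soil bacteria at regional scales.
- `simulate_geochip()` holds true category means constant across sites
  (functional convergence) unless `site_effect_sd > 0`, and layers on a
  per-sample lognormal scaling artefact, per-spot noise, and detection
  dropouts — exactly the artefacts the three-step pipeline is meant to
  remove.
- `simulate_environment()` builds soil (9 variables), climate (19
  bioclim-style variables) and plant-diversity columns from a latent
  factor model on the log scale, with factor 1 equal to standardised
  latitude and near-block loadings (climate on the latitudinal factor,
  soil on a fertility factor), then exponentiates; the log-PCA used in
  the workflow therefore recovers the factor structure.

What the generators do **not** emulate: real taxonomic abundance
distributions (no long-tailed richness of tens of thousands of OTUs),
sequencing error and chimeras, spatial autocorrelation beyond the single
latitudinal gradient, probe cross-hybridisation, or correlated
environmental noise. Passing tests therefore demonstrate that the
estimators and pipelines are correct and calibrated under their stated
assumptions — not that those assumptions hold in any particular field
data set.

## Workflow defaults and problem sizes

`run_endemism_analysis()` composes: align → remove singletons → rarefy
(20,000) → Bray-Curtis → DCA of relative abundances → per-taxon decay
(all sequences plus four phyla) → single matrix regressions per factor
plus one joint multiple regression. `run_function_analysis()` composes:
align → three-step pipeline → PCA of $\ln(x+1)$ category sums → DCA of
the log sums → single matrix regressions of each function PC difference
on the same factors (plus community dissimilarity when supplied). The
single and multiple regressions are reported separately and labelled,
never merged into one table. Every run records provenance: seed,
parameters, an input hash, and a step log; re-running with the same seed
reproduces the report exactly.

Sizes used by the shipped checks, chosen to characterise behaviour well
inside a few minutes on one CPU: estimator recovery on 24–105 pair
configurations with 200 seeds; null calibration on 15-sample matrices
with B = 199 over 1,000 replicates; the end-to-end contrast on the full
240-sample preset over 50 seeds with B = 199 bootstrap and reduced
permutation counts (observed R², not permutation p, is what that check
reads). The acceptance script runs the full preset once at B = 9,999
bootstrap and 999 permutations.

## Known limitations

- DCA omits nonlinear rescaling; axis *units* are not comparable to
  DECORANA's "SD of species turnover".
- Pair-level bootstrap and Mantel permutation both treat pairs as the
  analysis unit; neither corrects for the dependence structure of
  distance matrices beyond the permutation scheme itself.
- The z estimator conditions on $S > 0$; at extreme turnover (many
  completely disjoint pairs) the conditional fit underestimates true
  turnover, visible in `n_dropped`.
- BIOM support covers the JSON (1.0) dialect via `biomformat`; HDF5 BIOM
  2.x files are out of scope.
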