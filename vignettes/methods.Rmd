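---
title: "Methods: shape, mixture and diet inference in pigtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shape, mixture and diet inference in pigtrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pigtrace)
```

`pigtrace` implements the combined geometric-morphometric and
stable-isotope workflow used to study pig domestication and husbandry in
archaeological assemblages. This vignette documents the models, the
numerical choices, and the limits of what the synthetic-data tests show.

## Procrustes superimposition and centroid size

Configurations are superimposed by generalized Procrustes analysis:
each configuration is centred, scaled to unit centroid size
(`CS = sqrt(sum of squared distances to the centroid)`), and rotated onto
an iteratively re-estimated consensus by the SVD solution of the
orthogonal Procrustes problem. We use *partial* Procrustes — shapes stay
at unit centroid size, with no final `cos(rho)` rescaling — which keeps
size strictly in `CS` and shape strictly in the aligned coordinates.
Reflections are disallowed by default: left/right antimeres must be
mirrored before analysis, because silently allowing improper rotations
can hide digitization-side errors. The consensus loop stops when the
root-summed-squared change falls below `1e-10` (default), and alignment
is idempotent to `1e-9`.

Aligned coordinates are defined only up to one global rotation of the
whole set (the consensus orientation is anchored to the first specimen's
initial orientation); all downstream statistics are invariant to it.

## Semi-landmark sliding

Outline semi-landmarks carry no point-to-point homology along the curve,
so their tangential position is treated as a nuisance parameter. For each
specimen we estimate tangent directions by the central finite difference
through each semi-landmark's two outline neighbours (one-sided at open
ends) and minimize the thin-plate-spline bending energy of the specimen
relative to the current consensus, restricted to tangential
displacements. With bending-energy matrix `B` of the consensus (the
upper-left block of the inverse bordered-kernel system, kernel
`U(r) = r^2 log r^2`), the restricted problem is an unconstrained
quadratic in the sliding amounts and is solved exactly in closed form, so
each pass can only lower the energy at fixed consensus. After each pass
the set is re-superimposed and the consensus refreshed; iteration control
is `max_iter = 10`, `tol = 1e-6` on the mean tangential displacement.
Because re-superimposition perturbs the reference, total energy can creep
by a sliver between passes and strict convergence is not guaranteed; a
non-converged run returns its last state with `converged = FALSE` rather
than failing, and the per-pass energy bookkeeping is returned for audit.
Fixed anatomical landmarks never slide.

## Allometry

Static allometry is tested by multivariate regression of the Procrustes
coordinates on log centroid size. The statistic is the percentage of
total shape variance predicted by size; significance comes from
permuting sizes across specimens (default 1000 runs) with the add-one
convention `p = (1 + #{perm >= obs}) / (1 + n_perm)`, so `p` is never 0
and the test is exact at its grid resolution. When correction is wanted,
the pooled *within-group* regression (both shape and log size centred
within groups, one common slope) supplies residuals that remove the
shared allometric component while preserving group mean differences. A
single pooled slope zeroes the pooled within-group covariance between
residuals and size exactly; it cannot zero each group's covariance
separately unless the groups truly share the slope — the model the
correction assumes.

## Group comparison: MANOVA, CVA, phenogram

MANOVA (Pillai and Wilks with their standard F approximations) and CVA
run on a reduced set of leading principal components. The number of PCs
is chosen by maximizing leave-one-out LDA accuracy over bootstrap
subsamples balanced to the smallest usable group (groups below 3 are set
aside), never exceeding the balanced group size minus one; among counts
within 0.01 of the maximal accuracy the smallest wins, which guards
against the dimensionality over-fitting that unbalanced discriminant
analysis invites. Canonical axes are scaled so the pooled within-group
covariance of the scores is the identity; consequently Euclidean
distances between group means in the full canonical space equal
Mahalanobis distances with respect to the pooled within-group covariance
of the same subspace, and these feed an unrooted neighbour-joining
phenogram (`ape::nj`; negative branch lengths clamped to zero with a
warning, as is standard). Axis orientation is fixed deterministically by
making each axis's largest-magnitude loading positive. Confidence
ellipses use the group mean and covariance with the chi-square(2)
quantile (90% by default).

## Mixture modelling and the BIC convention

The wild/domestic admixture screen and the δ¹³C grouping both use
Gaussian mixtures fitted by EM, with k-means++ seeded hard-assignment
initialization, five restarts, and convergence at `Δ log L < 1e-8`.
Univariate variance families are `equal` (df = 2G: G means, one variance,
G−1 weights) and `variable` (df = 3G−1); multivariate families combine
spherical/diagonal/full covariance shapes with equal/variable across
components. Model choice maximizes `BIC = 2 log L − df log n` — the
"higher is better" convention, under which a two-component equal-variance
univariate fit with `log L = −44.25`, `df = 4`, `n = 17` scores `−99.83`.

Unequal-variance mixtures have an unbounded likelihood at zero component
variance, and small samples readily offer near-duplicate points for such
spikes. We bar them with a relative variance floor: component variances
(diagonals) never drop below `2.5e-3` times the data variance per
dimension, i.e. component spreads of at least 5% of the data spread. On
unimodal and well-separated bimodal test data this reproduces `mclust`'s
selections exactly while keeping the EM itself elementary and auditable;
it is the one numerical guard the mixture code adds beyond textbook EM.

The admixture screen fits mixtures per site/phase group on the
standardized 3-D feature (log centroid size, shape PC1, PC2), with
candidate G of 1–2 and the diagonal families (small per-phase samples do
not support full covariances). A group is flagged when its best model has
G ≥ 2 *and* some component's size mode — mean ± 1 sd on the log
centroid-size scale — overlaps a user-designated wild reference size
range. One standard deviation delimits the mode's core; wider margins let
spurious splits of a purely domestic scatter brush a nearby wild range
and raise false alarms. The wild range itself is an analyst input that
should come from actual wild reference material and sit clearly above
domestic scatter, as wild suid molars do.

## The diet endmember model

Collagen δ¹³C is interpreted against two dietary endmembers. Plant
references: modern open-area C3 plants (−29 to −25‰, mean −26.5‰),
archaeological millet seeds (−11.9 to −9.6‰), modern millet leaves
(−14.6 to −12.3‰). Modern references receive the +1.5‰ fossil-fuel
(Suess) correction; archaeological seed values, already pre-industrial,
do not. All diet values receive the +5‰ protein-to-collagen enrichment.
The derived collagen ranges are therefore pure C3 (−22.5, −18.5)‰ with a
−20‰ anchor (from the −26.5‰ mean plant value, not the range midpoint),
millet seed (−6.9, −4.6)‰ and millet leaf (−8.1, −5.8)‰.

Classification partitions the collagen axis with no gaps or overlaps:
values at or below −25‰ indicate forest C3 input (canopy effect); up to
−18.5‰, a pure C3 diet; at or above the millet-leaf lower bound (−8.1‰ by
default, exposed as a parameter because "C4-dominant" has no canonical
cutoff), a C4-dominant diet; in between, a mixed diet. An indicative
millet fraction interpolates linearly between the −20‰ C3 anchor and the
midpoint of the seed and leaf collagen means, clamped to [0, 100]; these
thresholds describe trends, and the fraction is reported as descriptive
only, never as a quantitative diet estimate.

δ¹⁵N banding uses herbivore and carnivore baselines measured in the same
ecosystem (deer-like and tiger-like reference taxa). The omnivore band is
centred on the midpoint of the two baselines with half-width 1.75‰ (half
the midpoint of the 3–4‰ trophic step); values below are herbivore-like,
above carnivore-like. Centring the band between the baselines — rather
than hanging margins off each baseline — keeps an intermediate value such
as a badger's 7.7‰ (against baselines of 4.6 and 9.3‰) in the omnivore
band, matching how such intermediate values are read in practice.

Third-molar length above 37.9 mm classifies a specimen as wild-sized;
the cutoff itself falls on the domestic side (the convention follows the
phrase "above the cutoff"), and the value is a parameter since reported
thresholds vary around 37–38 mm. The weaning filter keeps specimens at
dental stage 10 or older to avoid the nursing δ¹⁵N offset; records
without a stage are retained flagged (or dropped in strict mode).

## Synthetic data: what it emulates, and what it does not

The generators define the study conditions the tests probe:

* `make_template_outline()` builds a deterministic bilobed closed curve
  (polar form `r = 1 + 0.3 cos 2θ`) standing in for a lower-molar crown
  in occlusal view, with fixed landmarks at curvature extrema and
  semi-landmarks equidistant in arc length (uniform within 1%).
* `simulate_shape_dataset()` adds, in a smooth deformation basis that has
  been projected orthogonal to the similarity group (so planted effects
  survive superimposition to first order): per-group drift along one
  trajectory field, optional divergence along an orthogonal field, a
  static allometric component proportional to log centroid size — exactly
  the model the allometry test fits, deliberately, so parameter recovery
  is a sharp test — and iid landmark noise; sizes are lognormal per group.
  The default six-phase preset (`xwg_shape_preset()`) drifts gradually
  with a size dip and one divergent phase, the signature the CVA stage
  must resolve.
* `simulate_isotope_dataset()` draws per-phase δ¹³C from Gaussian
  mixtures and δ¹⁵N from per-phase normals. The preset
  (`xwg_isotope_preset()`) places one strongly bimodal phase (components
  near −18.5 and −10.2‰, weights 0.65/0.35, n = 17 — spans matching the
  published descriptive ranges of a C3-fed and a millet-fed herd) among
  unimodal phases with gradually rising millet intake and trophic level.

These generators emulate the *statistical* structure — group separations,
drift, bimodality, allometry — not real data's measurement regime:
digitizing error is iid Gaussian rather than autocorrelated along the
outline, outlines are smooth analytic curves, sample sizes are balanced,
and isotope values have no taxon-specific baselines or diagenesis.
Passing tests therefore demonstrate that the estimators recover planted
truth under the assumed models at realistic effect sizes; they do not
validate the archaeological interpretation of any particular assemblage.

## Test problem sizes and calibration checks

Simulation-based checks were sized to be decisive yet quick: the
allometry type-I calibration uses 500 null datasets of 30 specimens with
199 permutations each (the rejection rule `p <= 0.05` is exact at 10/200
under exchangeability); slope recovery uses n = 200 with landmark noise
set so that noise contributes about 2% relative error, leaving the
estimator's own bias visible against a 5% bar; the admixture screen
controls use 50 replicate positive (two modes 3 within-group sd apart in
size, plus a shape offset) and negative groups of 30; mixture-selection
consistency uses 15–50 seeded replicates per scenario; NJ is checked
against a brute-force Q-matrix implementation on all random additive
matrices up to 7 taxa. MANOVA calibration runs 200 null datasets.

## Known limitations

* Sliding relaxes against the consensus only; minimum-Procrustes-distance
  sliding is not implemented.
* The EM mixture supports at most the diagonal/full families listed;
  no regularized covariance estimation beyond the variance floor.
* CVA assumes a non-singular pooled within-group covariance on the chosen
  PC subspace and refuses otherwise rather than pseudo-inverting.
* The diet model is two-endmember arithmetic by design; it does not
  attempt Bayesian multi-source mixing, and the millet fraction is
  descriptive.
* TPS input is 2-D only; 3-D records are rejected.
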