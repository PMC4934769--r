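# pigtrace

Combined dental geometric morphometrics and stable-isotope diet analysis
for tracing suid (*Sus scrofa*) domestication and husbandry change in
zooarchaeological assemblages.

Archaeozoologists working on pig domestication routinely combine two lines
of evidence from the same faunal assemblage:

* **tooth form** — 2-D landmark + outline semi-landmark configurations of
  the lower second molar, a phenotypic marker separating wild from domestic
  populations and tracking population history across chronological phases;
* **bone-collagen stable isotopes** — δ¹³C (‰ VPDB) separating C3 browse
  from C4 (millet) food chains, and δ¹⁵N (‰ AIR) tracking trophic level,
  which together resolve foddering and household-rearing practices.

`pigtrace` packages the full statistical pipeline behind that study design
as tested, reusable functions, together with seeded synthetic-data
generators that emulate the statistical structure of such assemblages so
every stage can be validated end to end without access to raw collections.

## What the package computes

**Shape side.** Generalized Procrustes superimposition (partial Procrustes:
translation, unit centroid-size scaling, optimal rotation, no reflections);
centroid size `CS = sqrt(Σᵢ ‖pᵢ − p̄‖²)`; sliding of outline semi-landmarks
along tangent directions by exact quadratic minimization of the
thin-plate-spline bending energy `E(v) = vᵀ B v` (kernel `U(r) = r² log r²`)
relative to the consensus; shape PCA; a permutation test for static
allometry (multivariate regression of Procrustes coordinates on log CS, %
variance predicted as statistic, add-one p-values); pooled within-group
allometric correction; MANOVA (Pillai and Wilks); canonical variate
analysis with leave-one-out cross-validated, balanced-subsample selection
of the number of leading PCs; Mahalanobis distances between group means;
an unrooted neighbour-joining phenogram; 90% confidence ellipses.

**Mixture side.** Gaussian mixture models fitted by EM (univariate
equal/unequal variance; multivariate spherical/diagonal/full ×
equal/variable) with model choice by the highest BIC on the
`BIC = 2 log L − df · log n` convention, used both for the wild/domestic
admixture screen on (log CS, PC1, PC2) per phase and for δ¹³C grouping
within phases.

**Isotope side.** A two-endmember diet model projecting plant δ¹³C
references into consumer collagen: modern C3 plants (−29 to −25‰, mean
−26.5‰) and modern millet leaves (−14.6 to −12.3‰) receive a +1.5‰
fossil-fuel (Suess) correction; archaeological millet seeds (−11.9 to
−9.6‰) do not; all receive the +5‰ diet-protein→collagen enrichment. The
resulting collagen ranges — pure C3 (−22.5, −18.5)‰ around a −20‰ mean,
millet seed (−6.9, −4.6)‰, millet leaf (−8.1, −5.8)‰ — drive a categorical
diet classification, with a −25‰ canopy threshold for forest C3 input, a
3–4‰ δ¹⁵N trophic step for herbivore/omnivore/carnivore banding against
ecosystem baselines, a 37.9 mm third-molar length cutoff for wild vs
domestic size, and a dental-stage weaning filter.

## Worked example

```r
library(pigtrace)

## diet endmember model: collagen ranges implied by the plant references
m <- diet_endmember_model()
endmember_collagen_range(m, "c3")          # -22.5 -18.5
endmember_collagen_range(m, "millet_seed") #  -6.9  -4.6
endmember_collagen_range(m, "millet_leaf") #  -8.1  -5.8

## synthetic assemblage with a bimodal Longshan-like phase
iso <- simulate_isotope_dataset(xwg_isotope_preset(), seed = 42)
fit <- cluster_d13C(iso$records[iso$records$phase == "phase3_Longshan", ],
                    seed = 42)
fit
#> mixture_fit: G = 2 (equal), loglik = -40.6859, n = 17, df = 4, BIC = -92.7046
round(fit$means[, 1], 1)
#> -18.0  -9.9          # a C3-fed herd next to a millet-foddered herd

phase_comparison(iso$records, "d13C")$anova_F
#> 7.21                  # phases differ in C4 intake

## shape pipeline on a drifting six-phase series
sim    <- simulate_shape_dataset(xwg_shape_preset(10), seed = 42)
shapes <- slide_semilandmarks(gpa_align(sim$configs),
                              default_sliding_spec(sim$configs[[1]]))
test_allometry(shapes, n_perm = 999, seed = 42)
#> allometry: 20.970% of shape variance predicted by log size, p = 0.001
size_summary(log(shapes$centroid_sizes), sim$truth$group)$anova_F
#> 15.08                 # the planted size trajectory is recovered
```

The two Longshan δ¹³C modes at −18.0‰ and −9.9‰ straddle the −18.5‰
"no millet" bound and the millet collagen band: the mixture separates a
predominantly C3-fed (wild-type) herd from a millet-foddered domestic herd
within one phase. `run_full_analysis(run_config(...))` chains every stage
and writes the full report bundle (size/ANOVA tables, admixture screen,
CVA scores and ellipses, Mahalanobis matrix + Newick phenogram, isotope
classification, mixture reports, isotope × M3-size cross-table, manifest)
as CSV/JSON/Newick; `inst/cli/pigtrace.R` is a thin command-line front end
with `simulate`, `shapes`, `isotopes` and `all` subcommands.

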