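Package: pigtrace
Title: Dental Geometric Morphometrics and Stable Isotope Analysis of Pig
    Domestication and Husbandry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for tracing suid domestication and
    husbandry change in zooarchaeological assemblages by combining
    landmark-based tooth-shape analysis with bone-collagen stable isotope
    diet inference. Provides TPS landmark file input/output, generalized
    Procrustes superimposition with thin-plate-spline bending-energy
    sliding of outline semi-landmarks, shape principal components,
    permutation tests for static allometry and pooled within-group
    allometric correction, MANOVA, canonical variate analysis with
    cross-validated dimensionality selection, Mahalanobis distances and
    neighbour-joining phenograms, Gaussian mixture model-based clustering
    with BIC model selection for wild/domestic admixture screening and
    delta-13C grouping, a C3/C4 (millet) diet endmember mixing model for
    bone collagen, and seeded synthetic data generators that emulate the
    statistical structure of such assemblages for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    jsonlite,
    MASS,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
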