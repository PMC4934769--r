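test_that("shape PCA conserves variance and matches a dense eigendecomposition", {
  ss <- make_test_shapes(N = 10, noise = 0.02, seed = 2)
  X <- shape_matrix(ss)
  pc <- shape_pca(ss)
  S <- cov(X)
  expect_equal(sum(pc$eigenvalues), sum(diag(S)), tolerance = 1e-10)
  expect_lt(max(abs(colMeans(pc$scores))), 1e-10)
  dense <- eigen(S, symmetric = TRUE)
  k <- sum(dense$values > 1e-12)
  expect_equal(pc$eigenvalues[1:k], dense$values[1:k], tolerance = 1e-8)
  for (j in 1:3) {
    sc <- drop(sweep(X, 2, colMeans(X)) %*% dense$vectors[, j])
    expect_equal(abs(cor(sc, pc$scores[, j])), 1, tolerance = 1e-8)
  }
  # all shapes equal -> all eigenvalues 0
  same <- gpa_align(rep(list(make_template_outline(2, 10)$points), 4))
  expect_lt(max(shape_pca(same)$eigenvalues), 1e-20)
  expect_error(shape_pca(X[1:2, ]), "at least 3")
})

test_that("size summary reproduces textbook ANOVA and the notch formula", {
  s <- size_summary(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(s$anova_F, 13.5, tolerance = 1e-12)
  expect_equal(s$anova_p, anova(lm(y ~ g, data.frame(
    y = c(1, 2, 3, 4, 5, 6), g = rep(c("a", "b"), each = 3))))$`Pr(>F)`[1])

  ident <- size_summary(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(ident$anova_F, 0)

  g4 <- size_summary(c(10, 11, 12, 13), rep("a", 4))
  iqr <- quantile(c(10, 11, 12, 13), 0.75) - quantile(c(10, 11, 12, 13), 0.25)
  expect_equal(g4$table$notch, 1.58 * unname(iqr) / sqrt(4))
  expect_true(is.na(g4$anova_F))  # single group: summary only
  expect_true(all(g4$table$q1 <= g4$table$median & g4$table$median <= g4$table$q3))
})

test_that("allometry test recovers a perfect size signal and obeys the add-one rule", {
  sim <- simulate_shape_dataset(
    list(list(label = "g", n = 30, size_mean = 10, size_sd = 0.2)),
    allometry = list(slope = 0.1), noise_sd = 0, seed = 7)
  ss <- gpa_align(sim$configs)
  res <- test_allometry(ss, n_perm = 99, seed = 1)
  expect_gt(res$pct_variance_predicted, 99.9)
  expect_equal(res$p_value, 1 / 100)  # smallest attainable: add-one rule
  expect_error(test_allometry(ss, n_perm = 0), "n_perm")

  # p can never be zero, even when observed is the global maximum
  nullsim <- simulate_shape_dataset(
    list(list(label = "g", n = 15, size_mean = 10, size_sd = 0.2)),
    allometry = list(slope = 0), noise_sd = 0.01, seed = 8)
  p <- test_allometry(gpa_align(nullsim$configs), n_perm = 19, seed = 2)$p_value
  expect_gt(p, 0)
  expect_lte(p, 1)
})

test_that("pooled within-group allometry correction orthogonalizes and preserves means", {
  # planted common slope: estimated pooled slope recovers it
  sim <- simulate_shape_dataset(
    list(list(label = "a", n = 60, size_mean = 8, size_sd = 0.25),
         list(label = "b", n = 60, size_mean = 12, size_sd = 0.25, drift = 0.1)),
    allometry = list(slope = 0.1), noise_sd = 0.001, seed = 9)
  ss <- gpa_align(sim$configs)
  grp <- sim$truth$group
  ra <- remove_allometry(ss, grp)
  cs_t <- centroid_size(sim$truth$template$points)
  planted <- sim$truth$allometry_vector * sim$truth$slope / cs_t
  rel_err <- sqrt(sum((ra$slope - planted)^2)) / sqrt(sum(planted^2))
  expect_lt(rel_err, 0.15)

  # exact least-squares orthogonality: pooled within-group covariance of
  # residuals with log size is zero
  z <- ra$log_size
  gm <- ave(z, grp)
  w_cov <- crossprod(ra$residuals - apply(ra$residuals, 2, ave, grp), z - gm)
  expect_lt(max(abs(w_cov)), 1e-8)

  # group mean differences survive correction (up to the removed component)
  X <- shape_matrix(ss)
  raw_gap <- colMeans(X[grp == "b", ]) - colMeans(X[grp == "a", ])
  res_gap <- colMeans(ra$residuals[grp == "b", ]) -
             colMeans(ra$residuals[grp == "a", ])
  expect_equal(res_gap, raw_gap, tolerance = 1e-12, ignore_attr = TRUE)

  # zero allometry: residuals equal the raw variables up to the (near-zero)
  # estimated component
  sim0 <- simulate_shape_dataset(
    list(list(label = "a", n = 30, size_mean = 10, size_sd = 0.2)),
    allometry = list(slope = 0), noise_sd = 0.01, seed = 10)
  ss0 <- gpa_align(sim0$configs)
  ra0 <- remove_allometry(ss0, rep("a", 30))
  expect_equal(ra0$residuals, shape_matrix(ss0) - outer(
    ra0$log_size - mean(ra0$log_size), ra0$slope), tolerance = 1e-12)

  expect_warning(remove_allometry(ss0, c("solo", rep("a", 29))), "size 1")
})

test_that("MANOVA agrees with the two-group Hotelling relation and detects separation", {
  set.seed(21)
  n1 <- 25; n2 <- 25; p <- 4
  X <- rbind(matrix(rnorm(n1 * p), n1), sweep(matrix(rnorm(n2 * p), n2), 2, -1.2))
  g <- rep(c("a", "b"), c(n1, n2))
  res <- manova_test(X, g)
  m1 <- colMeans(X[1:n1, ]); m2 <- colMeans(X[-(1:n1), ])
  Sp <- (cov(X[1:n1, ]) * (n1 - 1) + cov(X[-(1:n1), ]) * (n2 - 1)) / (n1 + n2 - 2)
  T2 <- (n1 * n2 / (n1 + n2)) * mahalanobis(m1, m2, Sp)
  expect_equal(res$pillai$statistic, T2 / (T2 + n1 + n2 - 2), tolerance = 1e-8)
  expect_equal(res$wilks$statistic, 1 / (1 + T2 / (n1 + n2 - 2)), tolerance = 1e-8)
  expect_lt(res$wilks$p, 0.001)

  # huge mean shift: Wilks -> 0
  Xbig <- rbind(X[1:n1, ], sweep(X[-(1:n1), ], 2, -50))
  expect_lt(manova_test(Xbig, g)$wilks$statistic, 1e-3)

  expect_error(manova_test(matrix(rnorm(80), 10), rep(c("a", "b"), 5)),
               "reduce dimensionality")
})

test_that("MANOVA type-I error is near nominal under the null", {
  rej <- vapply(1:200, function(s) {
    set.seed(s + 3000)
    X <- matrix(rnorm(60 * 3), 60)
    manova_test(X, rep(c("a", "b", "c"), each = 20))$wilks$p <= 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.05 - 1.96 * sqrt(0.05 * 0.95 / 200) - 1e-9)
  expect_lt(mean(rej), 0.05 + 1.96 * sqrt(0.05 * 0.95 / 200) + 1e-9)
})

test_that("PC count selection finds a single discriminating axis and balances draws", {
  set.seed(31)
  n <- 30
  scores <- cbind(c(rnorm(n), rnorm(n, 6)), matrix(rnorm(2 * n * 5), 2 * n))
  g <- rep(c("a", "b"), each = n)
  k <- select_pc_count(scores, g, n_boot = 20, seed = 1)
  acc <- attr(k, "accuracy")
  expect_identical(as.integer(k), 1L)
  expect_gt(acc[1], 0.95)

  # pure noise: accuracy stays near chance for every candidate count
  noise <- matrix(rnorm(2 * n * 6), 2 * n)
  k0 <- select_pc_count(noise, g, n_boot = 20, seed = 2)
  expect_true(all(abs(attr(k0, "accuracy") - 0.5) < 0.2))

  # cap: never exceeds the balanced group size minus one
  small_g <- rep(c("a", "b"), c(40, 5))
  ks <- select_pc_count(matrix(rnorm(45 * 10), 45), small_g, n_boot = 5, seed = 3)
  expect_lte(as.integer(ks), 4L)

  # groups below 3 are excluded with a flag
  g3 <- c(rep("a", 20), rep("b", 20), rep("c", 2))
  k3 <- select_pc_count(rbind(scores[1:40, ], scores[1:2, ]), g3,
                        n_boot = 5, seed = 4)
  expect_identical(attr(k3, "excluded_groups"), "c")
})

test_that("CVA normalizes within-group covariance and recovers known geometry", {
  set.seed(41)
  X <- rbind(cbind(rnorm(120), rnorm(120), rnorm(120)),
             cbind(rnorm(120, 10), rnorm(120), rnorm(120)))
  g <- rep(c("a", "b"), each = 120)
  res <- cva(X, g)
  # pooled within-group covariance of scores = identity
  sc <- res$scores
  Sw <- (cov(sc[1:120, , drop = FALSE]) * 119 +
         cov(sc[-(1:120), , drop = FALSE]) * 119) / 238
  expect_equal(unname(as.matrix(Sw)), diag(ncol(sc)), tolerance = 1e-6)
  expect_equal(res$mahalanobis["a", "b"], 10, tolerance = 0.8)
  expect_equal(res$cv_accuracy, 1)

  # identical groups: leading eigenvalue ~ 0 relative to separated case
  same <- rbind(X[1:120, ], X[1:120, ])
  res0 <- cva(same, g)
  expect_lt(res0$eigenvalues[1], 1)

  # Mahalanobis invariant to invertible linear transforms at full rank
  set.seed(42)
  A <- matrix(rnorm(9), 3, 3) + diag(3)
  resT <- cva(X %*% A, g)
  expect_equal(resT$mahalanobis, res$mahalanobis, tolerance = 1e-6)

  # axis ordering by decreasing eigenvalue
  set.seed(43)
  X3 <- rbind(cbind(rnorm(50), rnorm(50)), cbind(rnorm(50, 4), rnorm(50)),
              cbind(rnorm(50, 2), rnorm(50, 3)))
  res3 <- cva(X3, rep(c("a", "b", "c"), each = 50))
  expect_true(all(diff(res3$eigenvalues) <= 1e-12))
  expect_error(cva(X, g, n_pc = 9), "exceeds")
})

test_that("NJ phenogram matches the closed form and the brute-force oracle", {
  D3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  nj3 <- nj_phenogram(D3)
  tip_edges <- nj3$tree$edge[, 2] <= 3
  lens <- nj3$tree$edge.length[tip_edges]
  names(lens) <- nj3$tree$tip.label[nj3$tree$edge[tip_edges, 2]]
  expect_equal(lens[c("A", "B", "C")], c(A = 1, B = 1, C = 3))

  # additive matrices up to 7 taxa: package tree metric == input == oracle
  for (n_taxa in c(4, 5, 6, 7)) {
    for (s in 1:5) {
      D <- random_additive_matrix(n_taxa, seed = 100 * n_taxa + s)
      res <- nj_phenogram(D)
      coph <- ape::cophenetic.phylo(res$tree)
      coph <- coph[rownames(D), colnames(D)]
      expect_equal(coph, D, tolerance = 1e-8)
      expect_equal(brute_nj_metric(D)[rownames(D), colnames(D)], D,
                   tolerance = 1e-8)
    }
  }

  # unrooted topology invariant to taxon order
  D <- random_additive_matrix(6, seed = 77)
  perm <- c(3, 1, 6, 2, 5, 4)
  t1 <- nj_phenogram(D)$tree
  t2 <- nj_phenogram(D[perm, perm])$tree
  expect_equal(ape::cophenetic.phylo(t2)[rownames(D), rownames(D)],
               ape::cophenetic.phylo(t1)[rownames(D), rownames(D)],
               tolerance = 1e-8)

  expect_error(nj_phenogram(D[1:2, 1:2]), "3 taxa")
  Dbad <- D; Dbad[1, 2] <- Dbad[1, 2] + 1
  expect_error(nj_phenogram(Dbad), "symmetric")
})

test_that("confidence ellipses hit the chi-square radius and nominal coverage", {
  set.seed(51)
  P <- matrix(rnorm(4e4), ncol = 2)
  e <- confidence_ellipse(P, 0.9)
  expect_equal(e$axes, rep(sqrt(qchisq(0.9, 2)), 2), tolerance = 0.03)
  inside <- mahalanobis(P, e$center, e$cov) <= qchisq(0.9, 2)
  expect_equal(mean(inside), 0.9, tolerance = 0.006)

  e0 <- confidence_ellipse(P[1:100, ], 0)
  expect_equal(unname(e0$axes), c(0, 0))

  line <- cbind(1:10, 2 * (1:10))
  expect_true(confidence_ellipse(line)$degenerate)
  expect_error(confidence_ellipse(P[1:2, ]), "3 points")
})
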