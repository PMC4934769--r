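test_that("centroid size matches its defining formula and invariances", {
  sq <- matrix(c(1, 1, 1, -1, -1, -1, -1, 1), ncol = 2, byrow = TRUE)
  expect_equal(centroid_size(sq), sqrt(8))
  expect_equal(centroid_size(sweep(sq, 2, c(-100, 7))), sqrt(8))

  set.seed(3)
  P <- matrix(rnorm(80, sd = 2), ncol = 2)
  brute <- sqrt(sum(apply(P, 1, function(p) sum((p - colMeans(P))^2))))
  expect_equal(centroid_size(P), brute, tolerance = 1e-12)
  expect_equal(centroid_size(3 * P), 3 * centroid_size(P), tolerance = 1e-12)

  expect_error(centroid_size(matrix(1, 5, 2)), "degenerate")
})

test_that("GPA removes position, scale and orientation and is idempotent", {
  set.seed(8)
  P <- matrix(rnorm(40), 20, 2)
  th <- 37 * pi / 180
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  ss <- gpa_align(list(P, 3 * P %*% R + 5, P))
  d12 <- sqrt(sum((ss$aligned[, , 1] - ss$aligned[, , 2])^2))
  expect_lt(d12, 1e-9)
  # identical copies: zero pairwise distance, consensus = standardized shape
  expect_equal(ss$aligned[, , 1], ss$aligned[, , 3], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(ss$consensus, ss$aligned[, , 1], tolerance = 1e-8,
               ignore_attr = TRUE)
  # ShapeSet invariants: centred, unit centroid size
  for (i in 1:3) {
    expect_lt(max(abs(colMeans(ss$aligned[, , i]))), 1e-8)
    expect_equal(sqrt(sum(ss$aligned[, , i]^2)), 1, tolerance = 1e-8)
  }
  ss2 <- gpa_align(ss)
  expect_equal(ss2$aligned, ss$aligned, tolerance = 1e-9)
})

test_that("GPA consensus fit beats alignment to any single fixed reference", {
  set.seed(9)
  base <- make_template_outline(2, 10)$points
  shapes <- lapply(1:20, function(i) base + matrix(rnorm(24, sd = 0.05), ncol = 2))
  ss <- gpa_align(shapes)
  m_gpa <- apply(ss$aligned, c(1, 2), mean)
  gpa_ss <- sum(vapply(1:20, function(i)
    sum((ss$aligned[, , i] - m_gpa)^2), numeric(1)))
  cs_norm <- function(P) { P <- sweep(P, 2, colMeans(P)); P / sqrt(sum(P^2)) }
  rotate_onto <- function(A, B) {
    s <- svd(crossprod(A, B)); R <- s$u %*% t(s$v)
    if (det(R) < 0) { s$u[, 2] <- -s$u[, 2]; R <- s$u %*% t(s$v) }
    A %*% R
  }
  for (ref_i in c(1, 7, 20)) {
    ref <- cs_norm(shapes[[ref_i]])
    ali <- lapply(shapes, function(P) rotate_onto(cs_norm(P), ref))
    m <- Reduce(`+`, ali) / 20
    ref_ss <- sum(vapply(ali, function(A) sum((A - m)^2), numeric(1)))
    expect_lte(gpa_ss, ref_ss + 1e-12)
  }
})

test_that("bending energy annihilates affine fields and matches the TPS quadratic form", {
  tmpl <- make_template_outline(2, 12)
  Be <- bending_energy_matrix(tmpl$points)
  n <- nrow(tmpl$points)

  en <- function(disp) drop(crossprod(disp[, 1], Be %*% disp[, 1]) +
                            crossprod(disp[, 2], Be %*% disp[, 2]))
  # translation and shear are affine: zero energy
  expect_lt(abs(en(matrix(rep(c(2, -1), n), ncol = 2, byrow = TRUE))), 1e-10)
  shear <- tmpl$points %*% matrix(c(1, 0.7, 0, 1), 2, 2) - tmpl$points
  expect_lt(abs(en(shear)), 1e-10)
  # positive semi-definite
  expect_gt(min(eigen((Be + t(Be)) / 2, symmetric = TRUE)$values), -1e-10)

  # non-affine field: agrees with the literal spline-coefficient evaluation
  set.seed(4)
  P10 <- matrix(runif(20, -1, 1), 10, 2)
  Be10 <- bending_energy_matrix(P10)
  disp <- matrix(rnorm(20, sd = 0.1), 10, 2)
  mine <- drop(crossprod(disp[, 1], Be10 %*% disp[, 1]) +
               crossprod(disp[, 2], Be10 %*% disp[, 2]))
  expect_equal(mine, brute_tps_energy(P10, disp), tolerance = 1e-8)

  expect_error(bending_energy_matrix(rbind(P10, P10[1, ])), "singular")
})

test_that("sliding is a no-op without semi-landmarks and leaves fixed points alone", {
  ss <- make_test_shapes(N = 8, noise = 0.01, seed = 5)
  spec0 <- sliding_spec(integer(0), matrix(integer(0), 0, 2))
  out0 <- slide_semilandmarks(ss, spec0)
  expect_equal(out0$aligned, ss$aligned)

  sim <- simulate_shape_dataset(
    list(list(label = "g", n = 6, size_mean = 10, size_sd = 0.05)),
    n_fixed = 2, n_semi = 14, noise_sd = 0.008, seed = 6)
  ss1 <- gpa_align(sim$configs)
  spec <- default_sliding_spec(sim$configs[[1]], max_iter = 3)
  out <- slide_semilandmarks(ss1, spec)
  # fixed landmarks: only similarity re-superimposition may move them, so
  # their within-shape distance to each other is preserved exactly by the
  # slide step itself; check energy bookkeeping exists and passes sanity
  expect_true(is.matrix(out$energy_history))
  expect_true(all(out$energy_history[, "after"] <=
                  out$energy_history[, "before"] + 1e-12))
})

test_that("one-semi-landmark sliding reaches the dense line-search optimum", {
  tmpl <- make_template_outline(2, 14)
  n <- nrow(tmpl$points)
  jit_idx <- 8L  # a semi-landmark
  spec_full <- default_sliding_spec(tmpl)
  nb <- spec_full$neighbors[match(jit_idx, spec_full$semi), ]
  # specimen: template with that point nudged along its outline tangent
  tangent <- tmpl$points[nb[2], ] - tmpl$points[nb[1], ]
  tangent <- tangent / sqrt(sum(tangent^2))
  jittered <- tmpl$points
  jittered[jit_idx, ] <- jittered[jit_idx, ] + 0.08 * tangent

  Be <- bending_energy_matrix(tmpl$points)
  en <- function(P) {
    v <- P - tmpl$points
    drop(crossprod(v[, 1], Be %*% v[, 1]) + crossprod(v[, 2], Be %*% v[, 2]))
  }
  e0 <- en(jittered)
  # package minimizer restricted to the jittered point
  shapes <- list(aligned = array(c(tmpl$points, jittered),
                                 dim = c(n, 2, 2)),
                 centroid_sizes = c(1, 1), consensus = tmpl$points,
                 ids = c("a", "b"), meta = NULL,
                 fixed = tmpl$fixed, semi = tmpl$semi)
  class(shapes) <- "shape_set"
  # one pass against the fixed template consensus, single sliding point
  spec1 <- sliding_spec(jit_idx, matrix(nb, 1, 2), max_iter = 1)
  out <- slide_semilandmarks(shapes, spec1)
  e1 <- unname(out$energy_history[1, "after"])
  expect_lt(e1, out$energy_history[1, "before"])
  # dense brute-force line search along the tangent for the second specimen
  tg <- jittered[nb[2], ] - jittered[nb[1], ]
  tg <- tg / sqrt(sum(tg^2))
  grid <- seq(-0.15, 0.05, length.out = 4001)
  brute <- min(vapply(grid, function(w) {
    P <- jittered; P[jit_idx, ] <- P[jit_idx, ] + w * tg; en(P)
  }, numeric(1)))
  # energy_history "after" totals both specimens; specimen 1 contributes ~0
  expect_equal(e1, brute, tolerance = 1e-4)
})

test_that("sliding then aligning is invariant to specimen relabeling", {
  sim <- simulate_shape_dataset(
    list(list(label = "g", n = 7, size_mean = 10, size_sd = 0.05)),
    n_fixed = 2, n_semi = 12, noise_sd = 0.01, seed = 12)
  spec <- default_sliding_spec(sim$configs[[1]], max_iter = 2)
  out1 <- slide_semilandmarks(gpa_align(sim$configs), spec)
  perm <- c(4, 1, 7, 3, 6, 2, 5)
  out2 <- slide_semilandmarks(gpa_align(sim$configs[perm]), spec)
  # aligned coordinates are defined up to one global rotation of the whole
  # set, so compare rotation-invariant inter-landmark geometry per specimen
  gram <- function(P) tcrossprod(sweep(P, 2, colMeans(P)))
  for (i in seq_along(perm))
    expect_equal(gram(out2$aligned[, , i]), gram(out1$aligned[, , perm[i]]),
                 tolerance = 1e-6, ignore_attr = TRUE)
})
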