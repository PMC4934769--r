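# Independent oracles used across the suite. These deliberately re-derive
# results by the most literal route available (agglomerative bookkeeping,
# dense grids, explicit matrix assembly) and share no code with the package
# internals they check.

# Brute-force neighbour joining: quadratic scan of the Q-matrix with
# lowest-(row, col) tie-breaking. Returns the tree metric (leaf-to-leaf path
# length matrix) rather than a tree object, so comparison needs no tree
# library.
brute_nj_metric <- function(D) {
  n <- nrow(D)
  labels <- rownames(D)
  # per active node: named vector of distances from each descendant leaf
  under <- lapply(labels, function(l) stats::setNames(0, l))
  tree_d <- matrix(0, n, n, dimnames = list(labels, labels))
  D <- unname(D)
  active <- seq_len(n)
  record_join <- function(i, j, li, lj) {
    for (a in names(under[[i]])) for (b in names(under[[j]])) {
      d <- under[[i]][a] + li + lj + under[[j]][b]
      tree_d[a, b] <<- d; tree_d[b, a] <<- d
    }
  }
  while (length(active) > 2L) {
    r <- length(active)
    Dsub <- D[active, active, drop = FALSE]
    R <- rowSums(Dsub)
    Q <- (r - 2) * Dsub - outer(R, R, `+`)
    diag(Q) <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- active[best[1]]; j <- active[best[2]]
    dij <- D[i, j]
    li <- dij / 2 + (R[best[1]] - R[best[2]]) / (2 * (r - 2))
    lj <- dij - li
    record_join(i, j, li, lj)
    # new node distances (reuse slot i)
    newd <- (D[i, active] + D[j, active] - dij) / 2
    D[i, active] <- newd; D[active, i] <- newd
    under[[i]] <- c(under[[i]] + li, under[[j]] + lj)
    active <- setdiff(active, j)
  }
  if (length(active) == 2L)
    record_join(active[1], active[2], D[active[1], active[2]], 0)
  tree_d
}

# Random additive (tree) distance matrix on n taxa with positive branch
# lengths, built by random sequential taxon attachment.
random_additive_matrix <- function(n, seed) {
  set.seed(seed)
  # grow an edge-length matrix via recursive splitting of a random tree
  tr <- ape::rtree(n, rooted = FALSE, br = function(k) runif(k, 0.2, 2))
  D <- ape::cophenetic.phylo(tr)
  D[order(rownames(D)), order(colnames(D))]
}

# Literal TPS bending energy of mapping `ref` -> `ref + disp`: solve the
# bordered kernel system for the spline coefficients and evaluate the
# quadratic form w' K w per output coordinate.
brute_tps_energy <- function(ref, disp) {
  n <- nrow(ref)
  r2 <- as.matrix(stats::dist(ref))^2
  K <- ifelse(r2 > 0, r2 * log(r2), 0)
  Q <- cbind(1, ref)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3, 3)))
  total <- 0
  for (d in 1:2) {
    sol <- solve(L, c(disp[, d], rep(0, 3)))
    w <- sol[seq_len(n)]
    total <- total + drop(crossprod(w, K %*% w))
  }
  total
}

# quick aligned shape set for statistics tests: N perturbed copies of the
# bilobed template
make_test_shapes <- function(N = 20, noise = 0.01, seed = 1,
                             n_fixed = 2, n_semi = 14) {
  sim <- simulate_shape_dataset(
    list(list(label = "g", n = N, size_mean = 10, size_sd = 0.1)),
    n_fixed = n_fixed, n_semi = n_semi, noise_sd = noise, seed = seed)
  gpa_align(sim$configs)
}
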