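#' Principal component analysis of Procrustes shape coordinates
#'
#' Eigen-analysis of the specimen covariance matrix of the superimposed
#' coordinates (no variable scaling): the standard shape-space ordination.
#'
#' @param shapes a `shape_set` or an N x p matrix of shape variables.
#' @return List with `scores` (N x k), `eigenvalues`, `eigenvectors`
#'   (p x k), `center` and `total_variance` (= sum of eigenvalues = trace of
#'   the covariance matrix).
#' @export
shape_pca <- function(shapes) {
  X <- if (inherits(shapes, "shape_set")) shape_matrix(shapes) else as.matrix(shapes)
  if (nrow(X) < 3L) stop("need at least 3 specimens for a PCA", call. = FALSE)
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  list(scores = pc$x, eigenvalues = ev, eigenvectors = pc$rotation,
       center = pc$center, total_variance = sum(ev))
}

#' Group size summary with notched-boxplot statistics and ANOVA
#'
#' Per-group five-number summary plus the notch half-width
#' 1.58 IQR / sqrt(n) (the conventional 95% confidence interval of the
#' median used in notched boxplots), and a one-way ANOVA of size across
#' groups. With a single group only the summary is returned.
#'
#' @param sizes positive numeric vector (e.g. centroid sizes, possibly
#'   log-transformed by the caller).
#' @param groups group labels, same length as `sizes`.
#' @return List of class `size_summary`: `table` (data frame with n, median,
#'   q1, q3, min, max, notch), `anova_F`, `anova_p`, `df`.
#' @export
size_summary <- function(sizes, groups) {
  stopifnot(length(sizes) == length(groups))
  g <- factor(groups)
  tab <- do.call(rbind, lapply(split(sizes, g), function(v) {
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(n = length(v), median = q[2], q1 = q[1], q3 = q[3],
               min = min(v), max = max(v),
               notch = 1.58 * (q[3] - q[1]) / sqrt(length(v)))
  }))
  tab <- cbind(group = levels(g), tab)
  rownames(tab) <- NULL
  out <- list(table = tab, anova_F = NA_real_, anova_p = NA_real_, df = NULL)
  if (nlevels(g) >= 2L && all(tabulate(g) >= 2L)) {
    fit <- anova(lm(sizes ~ g))
    out$anova_F <- fit$`F value`[1]
    out$anova_p <- fit$`Pr(>F)`[1]
    out$df <- fit$Df
  }
  class(out) <- "size_summary"
  out
}

#' @export
print.size_summary <- function(x, ...) {
  print(x$table, ...)
  if (!is.na(x$anova_F))
    cat(sprintf("one-way ANOVA: F = %.4g, p = %.4g\n", x$anova_F, x$anova_p))
  invisible(x)
}

# % of total shape variance predicted by the regression on log centroid size
.allometry_pct <- function(Xc, z) {
  zc <- z - mean(z)
  szz <- sum(zc^2)
  if (szz == 0) return(0)
  b <- crossprod(Xc, zc) / szz          # p-vector of slopes
  100 * szz * sum(b^2) / sum(Xc^2)      # SS(fitted)/SS(total)
}

#' Permutation test for static allometry
#'
#' Multivariate regression of the Procrustes shape coordinates on log
#' centroid size; the test statistic is the percentage of total shape
#' variance predicted by size, and its significance is assessed by permuting
#' sizes across specimens. P-values use the add-one convention
#' p = (1 + #\{permuted >= observed\}) / (1 + n_perm), so p is never 0.
#'
#' @param shapes a `shape_set` (or list with `$x` matrix and `$size` vector).
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed for the permutation stream.
#' @return List of class `allometry_result`: `pct_variance_predicted`,
#'   `p_value`, `coefficients` (slope vector), `intercept`, `n_perm`.
#' @export
test_allometry <- function(shapes, n_perm = 1000L, seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  if (inherits(shapes, "shape_set")) {
    X <- shape_matrix(shapes); sz <- shapes$centroid_sizes
  } else {
    X <- as.matrix(shapes$x); sz <- shapes$size
  }
  if (any(sz <= 0)) stop("centroid sizes must be positive", call. = FALSE)
  z <- log(sz)
  Xc <- sweep(X, 2, colMeans(X))
  obs <- .allometry_pct(Xc, z)
  zc <- z - mean(z)
  b <- crossprod(Xc, zc) / sum(zc^2)
  perm_ge <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i)
      .allometry_pct(Xc, sample(z)), numeric(1)) >= obs)
  })
  structure(
    list(pct_variance_predicted = obs,
         p_value = (1 + perm_ge) / (1 + n_perm),
         coefficients = drop(b),
         intercept = colMeans(X) - mean(z) * drop(b),
         n_perm = n_perm),
    class = "allometry_result")
}

#' @export
print.allometry_result <- function(x, ...) {
  cat(sprintf("allometry: %.3f%% of shape variance predicted by log size, p = %.4g (%d permutations)\n",
              x$pct_variance_predicted, x$p_value, x$n_perm))
  invisible(x)
}

#' Remove allometry by pooled within-group regression
#'
#' Regresses the shape variables on log centroid size with a common slope
#' estimated after centring both within groups (the pooled within-group
#' multivariate regression), and returns residual "allometry-free" shape
#' variables: the within-group allometric component is subtracted while
#' group mean differences are preserved. Groups of size 1 are excluded from
#' slope estimation with a warning.
#'
#' @param shapes a `shape_set` (or list with `$x` and `$size`).
#' @param groups group labels.
#' @return List: `residuals` (N x p matrix, same row order), `slope`
#'   (pooled within-group slope vector), `log_size`.
#' @export
remove_allometry <- function(shapes, groups) {
  if (inherits(shapes, "shape_set")) {
    X <- shape_matrix(shapes); sz <- shapes$centroid_sizes
  } else {
    X <- as.matrix(shapes$x); sz <- shapes$size
  }
  g <- factor(groups)
  z <- log(sz)
  counts <- tabulate(g)
  if (any(counts < 2L)) {
    warning("group(s) of size 1 excluded from pooled slope estimation: ",
            paste(levels(g)[counts < 2L], collapse = ", "))
  }
  use <- g %in% levels(g)[counts >= 2L]
  gm_x <- apply(X, 2, function(col) ave(col, g))
  gm_z <- ave(z, g)
  Xw <- (X - gm_x)[use, , drop = FALSE]
  zw <- (z - gm_z)[use]
  szz <- sum(zw^2)
  b <- if (szz > 0) drop(crossprod(Xw, zw) / szz) else rep(0, ncol(X))
  res <- X - outer(z - gm_z, b)
  rownames(res) <- rownames(X)
  list(residuals = res, slope = b, log_size = z)
}

#' MANOVA of shape variables across groups
#'
#' One-way multivariate analysis of variance with both the Pillai trace and
#' Wilks' lambda statistics and their standard F approximations (Rao's for
#' Wilks), as reported by standard software.
#'
#' @param vars N x p matrix of (shape) variables.
#' @param groups group labels.
#' @return List: `pillai`, `wilks`, each with `statistic`, `F`, `df` (num,
#'   den), `p`; plus `df_groups`.
#' @export
manova_test <- function(vars, groups) {
  X <- as.matrix(vars)
  g <- factor(groups)
  n <- nrow(X)
  if (n <= nlevels(g) + ncol(X))
    stop("too few specimens for ", ncol(X), " variables and ", nlevels(g),
         " groups: reduce dimensionality (e.g. fewer PCs) first", call. = FALSE)
  fit <- manova(X ~ g)
  if (qr(residuals(fit))$rank < ncol(X))
    stop("singular within-group covariance: reduce dimensionality first",
         call. = FALSE)
  grab <- function(test) {
    s <- summary(fit, test = test)$stats
    list(statistic = s[1, 2], F = s[1, 3], df = c(s[1, 4], s[1, 5]),
         p = s[1, 6])
  }
  list(pillai = grab("Pillai"), wilks = grab("Wilks"),
       df_groups = nlevels(g) - 1L)
}

#' Cross-validated choice of the number of principal components
#'
#' Selects how many leading PCs to feed the discriminant analysis by
#' maximizing leave-one-out LDA classification accuracy over bootstrap
#' subsamples balanced to equal size per group (the smallest usable group's
#' n), the usual guard against discriminant over-fitting with many shape
#' variables. Groups smaller than 3 are flagged and left out of the
#' selection. Among counts whose mean accuracy is within `plateau_tol` of
#' the maximum, the smallest is returned.
#'
#' @param scores N x k PCA score matrix.
#' @param groups group labels.
#' @param n_boot number of balanced subsamples per candidate count.
#' @param seed integer seed.
#' @param max_pc upper bound on candidate counts (further capped at the
#'   balanced sample size minus 2 and at min group n - 1).
#' @param plateau_tol accuracy tolerance defining the plateau.
#' @return Integer, with attributes `accuracy` (mean LOO accuracy per
#'   candidate count) and `excluded_groups`.
#' @export
select_pc_count <- function(scores, groups, n_boot = 50L, seed = 1L,
                            max_pc = NULL, plateau_tol = 0.01) {
  X <- as.matrix(scores)
  g <- factor(groups)
  counts <- table(g)
  excluded <- names(counts)[counts < 3L]
  keep <- !(g %in% excluded)
  X <- X[keep, , drop = FALSE]
  g <- droplevels(g[keep])
  if (nlevels(g) < 2L) stop("need at least 2 groups of size >= 3", call. = FALSE)
  n_bal <- min(table(g))
  k_max <- min(max_pc %||% ncol(X), ncol(X), n_bal - 1L,
               nlevels(g) * n_bal - nlevels(g) - 1L)
  k_max <- max(k_max, 1L)
  acc <- with_seed(seed, {
    vapply(seq_len(k_max), function(k) {
      mean(vapply(seq_len(n_boot), function(b) {
        idx <- unlist(lapply(levels(g), function(lv)
          sample(which(g == lv), n_bal)))
        sub_x <- X[idx, seq_len(k), drop = FALSE]
        sub_g <- g[idx]
        fit <- tryCatch(
          MASS::lda(sub_x, grouping = sub_g, CV = TRUE),
          error = function(e) NULL)
        if (is.null(fit)) return(NA_real_)
        mean(fit$class == sub_g)
      }, numeric(1)), na.rm = TRUE)
    }, numeric(1))
  })
  best <- which(acc >= max(acc, na.rm = TRUE) - plateau_tol)[1]
  structure(as.integer(best), accuracy = acc, excluded_groups = excluded)
}

#' Canonical variate analysis (multigroup LDA)
#'
#' Ordination maximizing between-group relative to pooled within-group
#' variation. Canonical axes are scaled so that the pooled within-group
#' covariance of the scores is the identity; squared Euclidean distances
#' between group means in the full score space are therefore Mahalanobis
#' distances with respect to the pooled within-group covariance of the same
#' variable subspace. Shape changes along each axis are recovered by
#' multivariate regression of the input variables on the canonical scores.
#'
#' @param vars N x p matrix of (shape) variables, e.g. leading PC scores.
#' @param groups group labels (each group >= 2).
#' @param n_pc number of leading columns of `vars` to use.
#' @return Object of class `cva_result`: `scores`, `eigenvalues`,
#'   `group_means` (in canonical space), `mahalanobis` (between-group
#'   distance matrix), `cv_accuracy` (leave-one-out LDA rate), `n_pc_used`,
#'   `axis_shape_changes` (p x n_axes regression coefficients), `axes`.
#' @export
cva <- function(vars, groups, n_pc = ncol(as.matrix(vars))) {
  X0 <- as.matrix(vars)
  if (n_pc > ncol(X0)) stop("n_pc exceeds available variables", call. = FALSE)
  X <- X0[, seq_len(n_pc), drop = FALSE]
  g <- factor(groups)
  if (any(tabulate(g) < 2L)) stop("every group needs >= 2 members", call. = FALSE)
  n <- nrow(X); k <- nlevels(g); p <- ncol(X)
  means <- do.call(rbind, lapply(split(seq_len(n), g), function(ix)
    colMeans(X[ix, , drop = FALSE])))
  Xc <- X - means[g, , drop = FALSE]
  W <- crossprod(Xc) / (n - k)                        # pooled within cov
  ew <- eigen(W, symmetric = TRUE)
  if (min(ew$values) < max(ew$values) * 1e-10)
    stop("singular pooled within-group covariance: use a smaller n_pc",
         call. = FALSE)
  Whalf_inv <- ew$vectors %*% diag(1 / sqrt(ew$values), p) %*% t(ew$vectors)
  grand <- colMeans(X)
  ns <- tabulate(g)
  Bss <- crossprod(sweep(means, 2, grand) * sqrt(ns))  # between SSCP
  M <- Whalf_inv %*% (Bss / (k - 1)) %*% Whalf_inv
  eb <- eigen((M + t(M)) / 2, symmetric = TRUE)
  s <- min(k - 1L, p)
  A <- Whalf_inv %*% eb$vectors[, seq_len(s), drop = FALSE]
  # deterministic axis orientation: largest-magnitude loading positive
  for (j in seq_len(s)) {
    lj <- A[, j]
    if (lj[which.max(abs(lj))] < 0) A[, j] <- -lj
  }
  scores <- sweep(X, 2, grand) %*% A
  colnames(scores) <- paste0("CV", seq_len(s))
  gm_scores <- sweep(means, 2, grand) %*% A
  D <- as.matrix(dist(gm_scores))
  cv_fit <- tryCatch(MASS::lda(X, grouping = g, CV = TRUE),
                     error = function(e) NULL)
  cv_acc <- if (is.null(cv_fit)) NA_real_ else mean(cv_fit$class == g)
  Sc <- sweep(scores, 2, colMeans(scores))
  Bcoef <- solve(crossprod(Sc), crossprod(Sc, sweep(X0, 2, colMeans(X0))))
  structure(
    list(scores = scores, eigenvalues = eb$values[seq_len(s)],
         group_means = gm_scores, mahalanobis = D, cv_accuracy = cv_acc,
         n_pc_used = n_pc, axis_shape_changes = t(Bcoef), axes = A,
         groups = g),
    class = "cva_result")
}

#' @export
print.cva_result <- function(x, ...) {
  cat("CVA:", ncol(x$scores), "canonical axes on", x$n_pc_used, "variables;",
      sprintf("LOO accuracy %.1f%%\n", 100 * x$cv_accuracy))
  invisible(x)
}

#' Unrooted neighbour-joining phenogram from a distance matrix
#'
#' Wraps the neighbour-joining algorithm (Saitou & Nei) as used for
#' phenograms of Mahalanobis distances between group mean shapes. Negative
#' branch lengths, which NJ can produce on non-additive matrices, are
#' clamped to zero with a warning, the standard practice.
#'
#' @param dist symmetric matrix with zero diagonal, >= 3 taxa.
#' @param labels taxon labels (defaults to the matrix dimnames).
#' @return List: `tree` (an `ape` `phylo`, unrooted) and `newick` (character).
#' @export
nj_phenogram <- function(dist, labels = NULL) {
  D <- as.matrix(dist)
  if (nrow(D) < 3L) stop("need at least 3 taxa", call. = FALSE)
  if (max(abs(D - t(D))) > 1e-8 || any(abs(diag(D)) > 1e-12))
    stop("dist must be symmetric with zero diagonal", call. = FALSE)
  if (!is.null(labels)) dimnames(D) <- list(labels, labels)
  if (is.null(rownames(D)))
    dimnames(D) <- list(paste0("t", seq_len(nrow(D))),
                        paste0("t", seq_len(nrow(D))))
  tree <- ape::nj(stats::as.dist(D))
  if (any(tree$edge.length < 0)) {
    warning("negative NJ branch length(s) clamped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  list(tree = tree, newick = ape::write.tree(tree))
}

#' Normal-theory confidence ellipse for 2-D scores
#'
#' Ellipse from the sample mean and covariance with the chi-square(2)
#' quantile at the requested probability level, as drawn around group
#' scatters in ordination plots.
#'
#' @param points n x 2 matrix, n >= 3.
#' @param level coverage probability (0.9 gives the conventional 90% ellipse).
#' @return List: `center`, `axes` (semi-axis lengths, major first), `angle`
#'   (radians, major axis vs x), `cov`, `level`, `degenerate` flag.
#' @export
confidence_ellipse <- function(points, level = 0.9) {
  P <- as.matrix(points)
  if (nrow(P) < 3L) stop("need at least 3 points", call. = FALSE)
  if (level < 0 || level >= 1) stop("level must be in [0, 1)", call. = FALSE)
  ctr <- colMeans(P)
  S <- cov(P)
  e <- eigen(S, symmetric = TRUE)
  degenerate <- min(e$values) <= max(e$values) * 1e-12
  r2 <- qchisq(level, df = 2)
  axes <- sqrt(pmax(e$values, 0) * r2)
  list(center = ctr, axes = axes,
       angle = atan2(e$vectors[2, 1], e$vectors[1, 1]),
       cov = S, level = level, degenerate = degenerate)
}
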