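#' Bayesian information criterion (higher-is-better convention)
#'
#' BIC = 2 log L - df log n, the convention under which the best model has
#' the highest BIC (as in `mclust`). For example a two-component
#' equal-variance univariate mixture fitted to 17 observations with
#' log-likelihood -44.25 and 4 free parameters scores -99.83.
#'
#' @param loglik maximized log-likelihood.
#' @param df number of free parameters (>= 0).
#' @param n number of observations (>= 1).
#' @return Numeric scalar.
#' @export
bic_score <- function(loglik, df, n) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (df < 0) stop("df must be >= 0", call. = FALSE)
  2 * loglik - df * log(n)
}

# free parameter counts per variance family
.gmm_df <- function(G, d, family) {
  base <- G * d + (G - 1)   # means + mixing weights
  varpar <- switch(family,
    equal = 1, variable = G,                       # univariate
    spherical_equal = 1, spherical_variable = G,
    diagonal_equal = d, diagonal_variable = G * d,
    full_equal = d * (d + 1) / 2, full_variable = G * d * (d + 1) / 2,
    stop("unknown family: ", family, call. = FALSE))
  base + varpar
}

# k-means++ center seeding
.kmeanspp <- function(X, G) {
  n <- nrow(X)
  centers <- X[sample.int(n, 1L), , drop = FALSE]
  while (nrow(centers) < G) {
    d2 <- apply(X, 1, function(x)
      min(colSums((t(centers) - x)^2)))
    if (sum(d2) == 0) {
      centers <- rbind(centers, X[sample.int(n, 1L), , drop = FALSE])
    } else {
      centers <- rbind(centers, X[sample.int(n, 1L, prob = d2), , drop = FALSE])
    }
  }
  centers
}

# log density of component g under the current parameters
.gmm_logdens <- function(X, mu, Sigma, family, d) {
  if (d == 1L) return(dnorm(X[, 1], mu[1], sqrt(Sigma[1, 1]), log = TRUE))
  ch <- chol(Sigma)
  z <- forwardsolve(t(ch), t(X) - mu)
  -0.5 * d * log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
}

# M-step covariance update under the structural constraints
.gmm_update_sigma <- function(X, resp, mu, family, d, floor) {
  G <- ncol(resp)
  nk <- colSums(resp)
  Ssum <- vector("list", G)
  for (g in seq_len(G)) {
    Xc <- sweep(X, 2, mu[g, ])
    Ssum[[g]] <- crossprod(Xc * resp[, g], Xc)
  }
  shape <- sub("_(equal|variable)$", "", family)
  if (family %in% c("equal", "variable")) shape <- "full"  # univariate
  equal <- grepl("equal$", family) || family == "equal"
  constrain <- function(S, w) {
    S <- S / w
    out <- switch(shape,
      spherical = diag(rep(mean(diag(S)), d), d),
      diagonal = diag(pmax(diag(S), floor), d),
      full = S)
    diag(out) <- pmax(diag(out), floor)
    out
  }
  if (equal) {
    Spool <- constrain(Reduce(`+`, Ssum), sum(nk))
    rep(list(Spool), G)
  } else {
    lapply(seq_len(G), function(g) constrain(Ssum[[g]], nk[g]))
  }
}

.gmm_em_once <- function(X, G, family, max_iter, tol, floor) {
  n <- nrow(X); d <- ncol(X)
  centers <- .kmeanspp(X, G)
  cl <- if (G == 1L) rep(1L, n) else tryCatch(
    suppressWarnings(kmeans(X, centers = centers, iter.max = 25L)$cluster),
    error = function(e)  # e.g. coincident centers: nearest-center fallback
      apply(X, 1, function(x) which.min(colSums((t(centers) - x)^2))))
  resp <- matrix(0, n, G)
  resp[cbind(seq_len(n), cl)] <- 1
  resp <- pmax(resp, 1e-6); resp <- resp / rowSums(resp)
  w <- colMeans(resp)
  loglik_trace <- numeric(0)
  ll_old <- -Inf
  mu <- NULL; Sig <- NULL
  for (it in seq_len(max_iter)) {
    nk <- colSums(resp)
    if (any(nk < 1e-8)) return(NULL)  # component collapse
    mu <- do.call(rbind, lapply(seq_len(G), function(g)
      colSums(X * resp[, g]) / nk[g]))
    Sig <- .gmm_update_sigma(X, resp, mu, family, d, floor)
    if (any(vapply(Sig, function(S) min(diag(S)) <= floor / 2, logical(1))))
      return(NULL)
    w <- nk / n
    logd <- vapply(seq_len(G), function(g)
      .gmm_logdens(X, mu[g, ], Sig[[g]], family, d) + log(w[g]),
      numeric(n))
    if (!is.matrix(logd)) logd <- matrix(logd, nrow = n)
    mx <- apply(logd, 1, max)
    lse <- mx + log(rowSums(exp(logd - mx)))
    ll <- sum(lse)
    loglik_trace <- c(loglik_trace, ll)
    resp <- exp(logd - lse)
    if (is.finite(ll_old) && ll - ll_old < tol && ll >= ll_old - 1e-8) break
    ll_old <- ll
  }
  list(mu = mu, Sigma = Sig, weights = w, resp = resp,
       loglik = loglik_trace[length(loglik_trace)],
       loglik_trace = loglik_trace)
}

#' Fit a Gaussian mixture by expectation-maximization
#'
#' Maximum-likelihood fit of a `G`-component Gaussian mixture with a
#' constrained variance structure. Univariate families: `"equal"` (one
#' shared variance; df = 2G) and `"variable"` (per-component variances;
#' df = 3G - 1). Multivariate families combine a covariance shape
#' (`spherical`, `diagonal`, `full`) with `equal`/`variable` across
#' components. Initialization is k-means++ followed by hard-assignment
#' k-means, with `n_restarts` seeded restarts keeping the best
#' log-likelihood; degenerate fits (component collapse) trigger a fresh
#' restart and the fit fails only if every restart collapses.
#'
#' @param data numeric vector (univariate) or N x d matrix.
#' @param G number of components (N > G).
#' @param family variance structure tag (see Details above).
#' @param seed integer seed.
#' @param max_iter,tol EM iteration control (tol on the log-likelihood
#'   increment).
#' @param n_restarts number of seeded initializations.
#' @return Object of class `mixture_fit`: `G`, `family`, `means`,
#'   `variances` (list of covariance matrices), `weights`, `loglik`, `df`,
#'   `bic`, `assignments`, `responsibilities`, `loglik_trace`, `n`.
#' @export
fit_gmm <- function(data, G, family = NULL, seed = 1L, max_iter = 500L,
                    tol = 1e-8, n_restarts = 5L) {
  X <- if (is.matrix(data)) data else matrix(as.numeric(data), ncol = 1L)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("data must be finite", call. = FALSE)
  n <- nrow(X); d <- ncol(X)
  if (n <= G) stop("need more observations than components", call. = FALSE)
  if (is.null(family)) family <- if (d == 1L) "equal" else "diagonal_variable"
  if (d == 1L && !family %in% c("equal", "variable"))
    stop("univariate families are 'equal' or 'variable'", call. = FALSE)
  if (d > 1L && family %in% c("equal", "variable"))
    stop("use spherical/diagonal/full _equal/_variable for multivariate data",
         call. = FALSE)
  # relative variance floor: bars the unbounded likelihood spikes that
  # near-singular components produce in unequal-variance mixtures
  floor_val <- 2.5e-3 * max(apply(X, 2, var), .Machine$double.eps)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      fit <- .gmm_em_once(X, G, family, max_iter, tol, floor_val)
      if (is.null(fit)) {  # collapsed: jitter and retry once within restart
        Xj <- X + matrix(rnorm(length(X), 0, sqrt(floor_val) * 10), n, d)
        fit <- .gmm_em_once(Xj, G, family, max_iter, tol, floor_val)
      }
      if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik))
        best <- fit
    }
  })
  if (is.null(best))
    stop("EM failed: component collapse in every restart", call. = FALSE)
  df <- as.integer(.gmm_df(G, d, family))
  ord <- order(best$mu[, 1])  # canonical component order
  structure(
    list(G = as.integer(G), family = family,
         means = best$mu[ord, , drop = FALSE],
         variances = best$Sigma[ord],
         weights = best$weights[ord],
         loglik = best$loglik, df = df,
         bic = bic_score(best$loglik, df, n),
         assignments = match(apply(best$resp, 1, which.max), ord),
         responsibilities = best$resp[, ord, drop = FALSE],
         loglik_trace = best$loglik_trace, n = n),
    class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("mixture_fit: G = %d (%s), loglik = %.4f, n = %d, df = %d, BIC = %.4f\n",
              x$G, x$family, x$loglik, x$n, x$df, x$bic))
  invisible(x)
}

#' Mixture model selection by highest BIC
#'
#' Fits every combination of component count and variance family and returns
#' the fit with the highest BIC (2 log L - df log n), keeping the full BIC
#' table for reporting.
#'
#' @param data numeric vector or matrix.
#' @param G_range candidate component counts.
#' @param families candidate variance family tags; defaults to both
#'   univariate families or the diagonal multivariate pair.
#' @param seed integer seed.
#' @param ... passed to [fit_gmm()].
#' @return The winning `mixture_fit`, with a `bic_table` data frame attached
#'   (`$bic_table`) covering every candidate (NA BIC for failed fits).
#' @export
select_model <- function(data, G_range = 1:3, families = NULL, seed = 1L, ...) {
  if (length(G_range) == 0L) stop("G_range must be non-empty", call. = FALSE)
  d <- if (is.matrix(data)) ncol(data) else 1L
  if (is.null(families))
    families <- if (d == 1L) c("equal", "variable")
                else c("diagonal_equal", "diagonal_variable")
  grid <- expand.grid(G = G_range, family = families,
                      stringsAsFactors = FALSE)
  fits <- vector("list", nrow(grid))
  errs <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    fits[[i]] <- tryCatch(
      fit_gmm(data, G = grid$G[i], family = grid$family[i],
              seed = seed + grid$G[i], ...),
      error = function(e) { errs[i] <<- conditionMessage(e); NULL })
  }
  bics <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$bic,
                 numeric(1))
  if (all(is.na(bics)))
    stop("all mixture fits failed:\n",
         paste(sprintf("G=%d %s: %s", grid$G, grid$family, errs),
               collapse = "\n"), call. = FALSE)
  best <- fits[[which.max(bics)]]
  best$bic_table <- cbind(grid, bic = bics,
                          loglik = vapply(fits, function(f)
                            if (is.null(f)) NA_real_ else f$loglik, numeric(1)),
                          df = vapply(fits, function(f)
                            if (is.null(f)) NA_integer_ else f$df, integer(1)))
  best
}

#' Wild/domestic admixture screen by per-group mixture modelling
#'
#' For each site/phase group, runs BIC model selection on the joint feature
#' (log centroid size, shape PC1, PC2) and flags groups whose best model has
#' two or more components with at least one size mode overlapping a wild
#' reference size range - the signature of wild specimens (or hybrids) mixed
#' into a domestic sample. Features are standardized internally; the flag is
#' evaluated on the log centroid size scale (component mean +/- 2 sd vs
#' `log(wild_size_range)`). Groups smaller than `min_n` are skipped.
#'
#' @param shapes a `shape_set`.
#' @param grouping per-specimen group labels (site/phase).
#' @param wild_size_range length-2 numeric: centroid size range of the wild
#'   reference phenotype.
#' @param G_range candidate component counts (default 1:2).
#' @param families candidate families (default diagonal pair).
#' @param seed integer seed.
#' @param min_n minimum group size screened.
#' @param flag_sd_mult how far a component's size mode extends for the
#'   overlap test, in component standard deviations (1 = the mode's core).
#' @return Data frame (class `admixture_screen`): one row per group with
#'   `n`, `G`, `family`, `bic`, `flagged`, `skipped`; per-group fits in
#'   `attr(, "fits")`.
#' @export
admixture_screen <- function(shapes, grouping, wild_size_range,
                             G_range = 1:2, families = c("diagonal_equal",
                                                         "diagonal_variable"),
                             seed = 1L, min_n = 5L, flag_sd_mult = 1) {
  pca <- shape_pca(shapes)
  feat <- cbind(log_cs = log(shapes$centroid_sizes),
                pc1 = pca$scores[, 1],
                pc2 = if (ncol(pca$scores) >= 2L) pca$scores[, 2] else 0)
  g <- factor(grouping)
  rows <- list(); fits <- list()
  for (lv in levels(g)) {
    idx <- which(g == lv)
    if (length(idx) < min_n) {
      message("admixture screen: group '", lv, "' skipped (n = ",
              length(idx), " < ", min_n, ")")
      rows[[lv]] <- data.frame(group = lv, n = length(idx), G = NA_integer_,
                               family = NA_character_, bic = NA_real_,
                               flagged = FALSE, skipped = TRUE)
      next
    }
    Xg <- feat[idx, , drop = FALSE]
    mu0 <- colMeans(Xg); sd0 <- apply(Xg, 2, sd)
    sd0[sd0 == 0] <- 1
    Z <- sweep(sweep(Xg, 2, mu0), 2, sd0, "/")
    fit <- select_model(Z, G_range = G_range, families = families, seed = seed)
    flagged <- FALSE
    if (fit$G >= 2L) {
      lo <- log(wild_size_range[1]); hi <- log(wild_size_range[2])
      for (comp in seq_len(fit$G)) {
        m_sz <- fit$means[comp, 1] * sd0[1] + mu0[1]
        s_sz <- sqrt(fit$variances[[comp]][1, 1]) * sd0[1]
        if (m_sz + flag_sd_mult * s_sz >= lo &&
            m_sz - flag_sd_mult * s_sz <= hi) flagged <- TRUE
      }
    }
    fits[[lv]] <- fit
    rows[[lv]] <- data.frame(group = lv, n = length(idx), G = fit$G,
                             family = fit$family, bic = fit$bic,
                             flagged = flagged, skipped = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  class(out) <- c("admixture_screen", "data.frame")
  out
}
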