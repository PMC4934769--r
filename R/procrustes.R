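#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of every landmark and
#' semi-landmark to the centroid (centre of gravity) of the configuration:
#' the standard geometric size measure, invariant to translation and rotation
#' and linear under uniform scaling.
#'
#' @param config a [landmark_config] or an n x 2 coordinate matrix.
#' @return Positive scalar.
#' @export
centroid_size <- function(config) {
  pts <- if (inherits(config, "landmark_config")) config$points else as.matrix(config)
  if (nrow(pts) < 2L) stop("need at least 2 points", call. = FALSE)
  ctr <- colMeans(pts)
  cs <- sqrt(sum(sweep(pts, 2, ctr)^2))
  if (cs == 0) stop("degenerate configuration: all points identical", call. = FALSE)
  cs
}

# coordinates of one config as a matrix
.pts <- function(x) if (inherits(x, "landmark_config")) x$points else as.matrix(x)

# optimal rotation of A onto B (both centred), reflections optionally barred
.opa_rotation <- function(A, B, allow_reflection = FALSE) {
  s <- svd(crossprod(A, B))
  R <- s$u %*% t(s$v)
  if (!allow_reflection && det(R) < 0) {
    u <- s$u
    u[, ncol(u)] <- -u[, ncol(u)]
    R <- u %*% t(s$v)
  }
  R
}

.center_scale <- function(P) {
  P <- sweep(P, 2, colMeans(P))
  P / sqrt(sum(P^2))
}

#' Generalized Procrustes superimposition
#'
#' Removes position, scale and orientation differences among a set of
#' landmark configurations by least-squares fitting to an iteratively updated
#' consensus (partial Procrustes: every shape is kept at unit centroid size,
#' with no final cos-rho rescaling). Reflections are disallowed by default;
#' antimeres should be mirrored before digitizing or via metadata.
#'
#' @param configs list of [landmark_config] objects (or n x 2 matrices) with
#'   a common point count, or an existing `shape_set` (re-alignment).
#' @param tol convergence tolerance on the consensus update (root summed
#'   squared change).
#' @param max_iter maximum consensus iterations.
#' @param allow_reflection allow improper rotations in the fit.
#' @return An object of class `shape_set`: `aligned` (n_pts x 2 x N array),
#'   `centroid_sizes`, `consensus` (centred, unit-size mean shape), `ids`,
#'   `meta`, `fixed`/`semi` role indices, and `iterations`.
#' @export
gpa_align <- function(configs, tol = 1e-10, max_iter = 200,
                      allow_reflection = FALSE) {
  if (inherits(configs, "shape_set")) {
    ss <- configs
    configs <- lapply(seq_len(dim(ss$aligned)[3]), function(i) ss$aligned[, , i])
    fixed <- ss$fixed; semi <- ss$semi; ids <- ss$ids; meta <- ss$meta
    sizes <- ss$centroid_sizes
  } else {
    fixed <- semi <- NULL; ids <- NULL; meta <- NULL; sizes <- NULL
    if (inherits(configs[[1]], "landmark_config")) {
      fixed <- configs[[1]]$fixed
      semi <- configs[[1]]$semi
      ids <- vapply(configs, function(cf) cf$specimen_id, character(1))
      meta <- lapply(configs, function(cf) cf$meta)
    }
  }
  mats <- lapply(configs, .pts)
  n_pts <- nrow(mats[[1]])
  if (n_pts < 3L) stop("need at least 3 landmarks", call. = FALSE)
  if (any(vapply(mats, nrow, integer(1)) != n_pts))
    stop("all configurations must share the same point count", call. = FALSE)
  N <- length(mats)
  if (is.null(sizes)) sizes <- vapply(mats, centroid_size, numeric(1))
  if (is.null(ids)) ids <- as.character(seq_len(N))
  if (is.null(fixed)) { fixed <- seq_len(n_pts); semi <- integer(0) }

  X <- lapply(mats, .center_scale)
  consensus <- X[[1]]
  iter <- 0L
  repeat {
    iter <- iter + 1L
    X <- lapply(X, function(P) P %*% .opa_rotation(P, consensus, allow_reflection))
    new_cons <- .center_scale(Reduce(`+`, X) / N)
    delta <- sqrt(sum((new_cons - consensus)^2))
    consensus <- new_cons
    if (delta < tol || iter >= max_iter) break
  }
  aligned <- array(unlist(X), dim = c(n_pts, 2L, N))
  dimnames(aligned) <- list(NULL, c("x", "y"), ids)
  structure(
    list(aligned = aligned, centroid_sizes = sizes, consensus = consensus,
         ids = ids, meta = meta, fixed = fixed, semi = semi,
         iterations = iter),
    class = "shape_set")
}

#' @export
print.shape_set <- function(x, ...) {
  cat("shape_set:", dim(x$aligned)[3], "specimens,", dim(x$aligned)[1],
      "landmarks (", length(x$semi), "sliding )\n")
  invisible(x)
}

#' Thin-plate-spline bending energy matrix
#'
#' Builds the bending energy matrix of a 2-D reference configuration from the
#' thin-plate-spline kernel U(r) = r^2 log r^2: the upper-left n x n block of
#' the inverse of the bordered kernel system. The quadratic form v' B v gives
#' the (integral) bending energy of a displacement field v per coordinate;
#' it is positive semi-definite and exactly annihilates affine displacement
#' fields of the reference.
#'
#' @param reference n x 2 matrix of distinct reference points.
#' @return Symmetric n x n matrix.
#' @export
bending_energy_matrix <- function(reference) {
  P <- .pts(reference)
  n <- nrow(P)
  if (n < 4L) stop("need at least 4 reference points", call. = FALSE)
  d2 <- as.matrix(dist(P))^2
  if (any(d2[upper.tri(d2)] == 0))
    stop("singular kernel: coincident reference points", call. = FALSE)
  K <- ifelse(d2 > 0, d2 * log(d2), 0)
  Q <- cbind(1, P)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3L, 3L)))
  Linv <- tryCatch(solve(L), error = function(e)
    stop("singular kernel system: degenerate reference configuration",
         call. = FALSE))
  Be <- Linv[seq_len(n), seq_len(n), drop = FALSE]
  (Be + t(Be)) / 2
}

# total TPS bending energy of `shape` relative to `ref`, given Be(ref)
.bending_energy <- function(Be, shape, ref) {
  v <- shape - ref
  drop(crossprod(v[, 1], Be %*% v[, 1]) + crossprod(v[, 2], Be %*% v[, 2]))
}

#' Sliding specification for outline semi-landmarks
#'
#' @param semi ordered indices of the semi-landmarks.
#' @param neighbors integer length(semi) x 2 matrix: for each semi-landmark
#'   the indices of its two outline neighbours, used for the central-finite-
#'   difference tangent estimate (one-sided at open-outline endpoints by
#'   repeating the point's own index on one side).
#' @param max_iter maximum slide/re-superimpose iterations.
#' @param tol convergence tolerance on the mean semi-landmark displacement.
#' @return An object of class `sliding_spec`.
#' @export
sliding_spec <- function(semi, neighbors, max_iter = 10L, tol = 1e-6) {
  semi <- as.integer(semi)
  neighbors <- matrix(as.integer(neighbors), ncol = 2L)
  if (length(semi) > 0L && nrow(neighbors) != length(semi))
    stop("neighbors must have one row per semi-landmark", call. = FALSE)
  if (max_iter < 1L) stop("max_iter must be >= 1", call. = FALSE)
  structure(list(semi = semi, neighbors = neighbors,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "sliding_spec")
}

#' Default sliding specification from outline ordering
#'
#' Builds a [sliding_spec] for a configuration whose points carry an
#' `outline_order` attribute (as produced by [make_template_outline()]) or,
#' failing that, assumes the points are already in outline order. The outline
#' is treated as closed.
#'
#' @param config a [landmark_config].
#' @inheritParams sliding_spec
#' @return A [sliding_spec].
#' @export
default_sliding_spec <- function(config, max_iter = 10L, tol = 1e-6) {
  n <- nrow(config$points)
  ord <- attr(config, "outline_order") %||% seq_len(n)
  pos <- match(seq_len(n), ord)   # position of each point along the outline
  nb <- cbind(ord[(pos - 2L) %% n + 1L], ord[pos %% n + 1L])
  sliding_spec(config$semi, nb[config$semi, , drop = FALSE],
               max_iter = max_iter, tol = tol)
}

#' Slide semi-landmarks by bending-energy minimization
#'
#' Iteratively relaxes outline semi-landmarks along their estimated tangent
#' directions so as to minimize the thin-plate-spline bending energy of each
#' specimen relative to the current consensus, re-superimposing and updating
#' the consensus after every pass. Each pass solves the exact quadratic
#' minimizer of the bending energy restricted to tangential displacements, so
#' the per-pass energy (at fixed consensus) can only decrease. Fixed
#' landmarks never move.
#'
#' @param shapes a `shape_set` from [gpa_align()].
#' @param spec a [sliding_spec]; if `NULL`, built from the first specimen's
#'   stored roles with consecutive outline ordering.
#' @return A `shape_set` with slid coordinates plus `converged` (logical),
#'   `slide_iterations`, and `energy_history` (total bending energy relative
#'   to the consensus before and after each sliding pass).
#' @export
slide_semilandmarks <- function(shapes, spec = NULL) {
  if (!inherits(shapes, "shape_set")) stop("shapes must be a shape_set", call. = FALSE)
  if (is.null(spec)) {
    n <- dim(shapes$aligned)[1]
    cfg <- landmark_config("consensus", shapes$consensus,
                           fixed = shapes$fixed, semi = shapes$semi)
    spec <- default_sliding_spec(cfg)
  }
  m <- length(spec$semi)
  if (m == 0L) {
    shapes$converged <- TRUE
    shapes$slide_iterations <- 0L
    shapes$energy_history <- numeric(0)
    return(shapes)
  }
  n_pts <- dim(shapes$aligned)[1]
  N <- dim(shapes$aligned)[3]
  energy_hist <- NULL
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(spec$max_iter)) {
    iters <- it
    cons <- shapes$consensus
    Be <- bending_energy_matrix(cons)
    e_before <- sum(vapply(seq_len(N), function(i)
      .bending_energy(Be, shapes$aligned[, , i], cons), numeric(1)))
    disp_total <- 0
    new_aligned <- shapes$aligned
    for (i in seq_len(N)) {
      P <- shapes$aligned[, , i]
      tg <- P[spec$neighbors[, 2], , drop = FALSE] -
            P[spec$neighbors[, 1], , drop = FALSE]
      tg_norm <- sqrt(rowSums(tg^2))
      tg_norm[tg_norm == 0] <- 1
      tg <- tg / tg_norm
      # E(w) = sum_d (v_d + T_d w)' Be (v_d + T_d w), T_d sparse tangent maps
      Tx <- matrix(0, n_pts, m); Ty <- matrix(0, n_pts, m)
      Tx[cbind(spec$semi, seq_len(m))] <- tg[, 1]
      Ty[cbind(spec$semi, seq_len(m))] <- tg[, 2]
      vx <- P[, 1] - cons[, 1]; vy <- P[, 2] - cons[, 2]
      BTx <- Be %*% Tx; BTy <- Be %*% Ty
      A <- crossprod(Tx, BTx) + crossprod(Ty, BTy)
      b <- -(crossprod(BTx, vx) + crossprod(BTy, vy))
      w <- tryCatch(solve(A, b), error = function(e) MASS::ginv(A) %*% b)
      P[spec$semi, ] <- P[spec$semi, , drop = FALSE] + drop(w) * tg
      disp_total <- disp_total + mean(abs(w))
      new_aligned[, , i] <- P
    }
    e_after <- sum(vapply(seq_len(N), function(i)
      .bending_energy(Be, new_aligned[, , i], cons), numeric(1)))
    energy_hist <- rbind(energy_hist, c(before = e_before, after = e_after))
    # re-superimpose and refresh consensus
    shapes_new <- gpa_align(lapply(seq_len(N), function(i) new_aligned[, , i]))
    shapes$aligned <- shapes_new$aligned
    dimnames(shapes$aligned) <- list(NULL, c("x", "y"), shapes$ids)
    shapes$consensus <- shapes_new$consensus
    if (disp_total / N < spec$tol) { converged <- TRUE; break }
  }
  shapes$converged <- converged || iters < spec$max_iter
  shapes$slide_iterations <- iters
  shapes$energy_history <- energy_hist
  shapes
}

#' Flatten a shape set to a specimen x coordinate matrix
#'
#' @param shapes a `shape_set`.
#' @return N x (2 n_pts) matrix, coordinates interleaved x1, y1, x2, y2, ...
#' @export
shape_matrix <- function(shapes) {
  N <- dim(shapes$aligned)[3]
  out <- t(vapply(seq_len(N), function(i) as.vector(t(shapes$aligned[, , i])),
                  numeric(2L * dim(shapes$aligned)[1])))
  rownames(out) <- shapes$ids
  out
}
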