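#' Importance-weight the columns of a scaled array
#'
#' Multiplies column `j` of the scaled feature array by weight `V[j]`
#' (direct multiplication, not square-root weighting). With uniform weights
#' the array is tagged `"prior"` (naive); with a blender-derived V it is the
#' `"posterior"`, accuracy-weighted array on which the predictive
#' unsupervised stages operate.
#'
#' @param scaled_X Numeric matrix (rows = observations).
#' @param weights Non-negative weights, one per column; `NULL` means uniform
#'   `1/p` (the prior array).
#' @param tag Optional explicit `"prior"`/`"posterior"` tag; inferred
#'   otherwise.
#' @return A `weighted_array`: the rescaled matrix with `weighting_tag` and
#'   `weight_vector` attributes.
#' @export
weight_columns <- function(scaled_X, weights = NULL, tag = NULL) {
  scaled_X <- as.matrix(scaled_X)
  p <- ncol(scaled_X)
  uniform <- is.null(weights)
  if (uniform) weights <- rep(1 / p, p)
  if (length(weights) != p) stop("one weight per column required")
  if (any(weights < 0)) stop("negative weights")
  out <- sweep(scaled_X, 2, as.numeric(weights), "*")
  structure(out,
            weighting_tag = tag %||% (if (uniform ||
                                          max(abs(weights - mean(weights))) <
                                            1e-12) "prior" else "posterior"),
            weight_vector = setNames(as.numeric(weights), colnames(scaled_X)),
            class = c("weighted_array", "matrix"))
}

#' Affinity-propagation clustering
#'
#' Message-passing clustering (responsibility/availability updates with
#' damping) on the negative squared Euclidean distance similarity. The
#' preference (self-similarity) defaults to the median pairwise similarity;
#' the number of clusters is not pre-specified but emerges from the
#' preference. The algorithm is deterministic given its parameters.
#'
#' @param x Numeric matrix of observations.
#' @param damping Damping factor in `[0.5, 1)`.
#' @param preference Diagonal self-similarity; default median of the
#'   off-diagonal similarities.
#' @param max_iter Iteration cap.
#' @param convits Stop after this many iterations with an unchanged exemplar
#'   set.
#' @param seed Seed for the infinitesimal similarity jitter that breaks
#'   exact degeneracies; the clustering is deterministic given it.
#' @return A `cluster_solution`: integer `labels` (1..K per row), `exemplars`
#'   (row indices), `n_clusters`, `damping`, `preference`, `iterations`.
#' @export
cluster_affinity <- function(x, damping = 0.5, preference = NULL,
                             max_iter = 1000, convits = 50, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) stop("need at least 2 observations")
  if (damping < 0.5 || damping >= 1) stop("damping must lie in [0.5, 1)")
  S <- -as.matrix(dist(x))^2
  if (is.null(preference)) preference <- median(S[lower.tri(S)])
  diag(S) <- preference
  # tiny seeded jitter breaks the degeneracies (duplicate rows, symmetric
  # configurations) that make the message passing oscillate
  set.seed(seed)
  scale_s <- max(1e-12, diff(range(S)))
  S <- S + scale_s * 1e-10 * matrix(rnorm(n * n), n, n)
  R <- A <- matrix(0, n, n)
  stable <- 0L
  prev_ex <- integer(0)
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # responsibilities
    AS <- A + S
    max1 <- apply(AS, 1, max)
    which1 <- max.col(AS, ties.method = "first")
    AS2 <- AS
    AS2[cbind(seq_len(n), which1)] <- -Inf
    max2 <- apply(AS2, 1, max)
    Rnew <- S - max1
    Rnew[cbind(seq_len(n), which1)] <- S[cbind(seq_len(n), which1)] - max2
    R <- damping * R + (1 - damping) * Rnew
    # availabilities
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    cs <- matrix(colSums(Rp), n, n, byrow = TRUE)
    Anew <- pmin(cs - Rp, 0)
    diag(Anew) <- colSums(pmax(R, 0)) - pmax(diag(R), 0)
    A <- damping * A + (1 - damping) * Anew
    ex <- which(diag(A) + diag(R) > 0)
    if (identical(ex, prev_ex) && length(ex) > 0) {
      stable <- stable + 1L
      if (stable >= convits) break
    } else {
      stable <- 0L
      prev_ex <- ex
    }
  }
  ex <- which(diag(A) + diag(R) > 0)
  if (length(ex) == 0 || (it >= max_iter && stable < convits))
    stop(sprintf(paste0("affinity propagation did not converge: %d ",
                        "iterations, %d candidate exemplars, preference ",
                        "%.4g; consider raising damping or max_iter"),
                 it, length(ex), preference))
  labels <- apply(S[, ex, drop = FALSE], 1, which.max)
  labels[ex] <- seq_along(ex)
  # refine: exemplar = member maximizing within-cluster similarity
  for (k in seq_along(ex)) {
    members <- which(labels == k)
    if (length(members) > 1) {
      sums <- colSums(S[members, members, drop = FALSE])
      ex[k] <- members[which.max(sums)]
    }
  }
  labels <- apply(S[, ex, drop = FALSE], 1, which.max)
  labels[ex] <- seq_along(ex)
  structure(list(labels = as.integer(labels), exemplars = ex,
                 n_clusters = length(ex), damping = damping,
                 preference = preference, iterations = it),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("cluster_solution: %d clusters over %d points (%d iterations)\n",
              x$n_clusters, length(x$labels), x$iterations))
  print(table(x$labels))
  invisible(x)
}

#' Dimensionality reduction by six methods
#'
#' One front door over principal component analysis (`"pca"`), classical
#' multidimensional scaling (`"mds"`), t-distributed stochastic neighbour
#' embedding (`"tsne"`), isometric feature mapping (`"isomap"`), locally
#' linear embedding (`"lle"`) and maximum-likelihood factor analysis
#' (`"factor"`). PCA dimensions are ordered by decreasing explained
#' variance; MDS carries a stress value
#' (\eqn{\sqrt{\sum (d - \hat d)^2 / \sum d^2}}) in the metadata.
#'
#' t-SNE (perplexity 30, 500 gradient iterations with early exaggeration)
#' and LLE (k-nearest-neighbour reconstruction with ridge-regularized local
#' weights) are implemented in-package; isomap delegates to
#' \pkg{vegan}.
#'
#' @param x Numeric matrix (or `weighted_array`).
#' @param method One of `pca`, `mds`, `tsne`, `isomap`, `lle`, `factor`.
#' @param k Target dimension (`k < ncol(x)`, `k < nrow(x)`).
#' @param seed Seed (t-SNE initialization; other methods deterministic).
#' @param perplexity,n_neighbors Method-specific tuning.
#' @return An `embedding`: `method`, `k`, `coordinates` (n x k), `seed`,
#'   `metadata`.
#' @export
embed_array <- function(x, method = c("pca", "mds", "tsne", "isomap", "lle",
                                      "factor"),
                        k = 2, seed = 1L, perplexity = 30, n_neighbors = 10) {
  method <- match.arg(method)
  x <- unclass(as.matrix(x))
  n <- nrow(x)
  if (k >= ncol(x)) stop("k must be smaller than the number of features")
  if (n <= k) stop("need more observations than dimensions")
  meta <- list()
  coords <- switch(method,
    pca = {
      pc <- prcomp(x, center = TRUE, scale. = FALSE)
      meta$explained_variance <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
      pc$x[, seq_len(k), drop = FALSE]
    },
    mds = {
      d <- dist(x)
      co <- smacof_mds(d, k = k, seed = seed)
      dhat <- dist(co)
      meta$stress <- sqrt(sum((d - dhat)^2) / sum(d^2))
      co
    },
    tsne = tsne_embed(x, k = k, perplexity = perplexity, seed = seed),
    isomap = {
      iso <- vegan::isomap(dist(x), ndim = k, k = n_neighbors)
      iso$points[, seq_len(k), drop = FALSE]
    },
    lle = lle_embed(x, k = k, n_neighbors = n_neighbors),
    factor = {
      fa <- factanal(x, factors = k, scores = "regression")
      meta$loadings <- unclass(fa$loadings)
      fa$scores[, seq_len(k), drop = FALSE]
    })
  coords <- as.matrix(coords)
  assert_finite(coords, "embedding coordinates")
  structure(list(method = method, k = k, coordinates = coords, seed = seed,
                 metadata = meta),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("embedding [%s]: %d x %d\n", x$method, nrow(x$coordinates),
              x$k))
  invisible(x)
}

# Metric MDS by SMACOF stress majorization: classical-scaling start with a
# small seeded jitter, then Guttman transforms until relative stress change
# drops below tolerance.
#' @noRd
smacof_mds <- function(d, k = 2, seed = 1L, max_iter = 300, tol = 1e-7) {
  D <- as.matrix(d)
  n <- nrow(D)
  init <- cmdscale(d, k = k)
  if (ncol(init) < k)
    stop("MDS could not produce the requested number of dimensions")
  set.seed(seed)
  Y <- init + matrix(rnorm(n * k, sd = 1e-6 * (max(D) + 1)), n, k)
  stress_of <- function(Y) {
    dy <- as.matrix(dist(Y))
    sum((D - dy)[lower.tri(D)]^2)
  }
  s_old <- stress_of(Y)
  for (it in seq_len(max_iter)) {
    dy <- as.matrix(dist(Y))
    ratio <- ifelse(dy > 0, D / dy, 0)
    B <- -ratio
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    Y <- B %*% Y / n
    s_new <- stress_of(Y)
    if (abs(s_old - s_new) <= tol * max(s_old, .Machine$double.eps)) break
    s_old <- s_new
  }
  Y
}

# t-SNE, standard formulation: perplexity-calibrated Gaussian input
# affinities, Student-t output kernel, gradient descent with momentum and
# early exaggeration.
#' @noRd
tsne_embed <- function(x, k = 2, perplexity = 30, seed = 1L,
                       n_iter = 500) {
  n <- nrow(x)
  perplexity <- min(perplexity, floor((n - 1) / 3))
  D2 <- as.matrix(dist(x))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { h <- 0; p[] <- 0 } else {
        h <- log(sp) + beta * sum(di * p) / sp
        p <- p / sp
      }
      if (abs(h - logU) < 1e-5) break
      if (h > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  set.seed(seed)
  Y <- matrix(rnorm(n * k, sd = 1e-4), n, k)
  dY <- matrix(0, n, k)
  momentum <- 0.5
  eta <- 200
  P4 <- P * 4  # early exaggeration
  for (it in seq_len(n_iter)) {
    Puse <- if (it <= 100) P4 else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Puse - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    if (it == 250) momentum <- 0.8
    dY <- momentum * dY - eta * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

# Locally linear embedding with ridge-regularized reconstruction weights.
#' @noRd
lle_embed <- function(x, k = 2, n_neighbors = 10) {
  n <- nrow(x)
  n_neighbors <- min(n_neighbors, n - 1)
  D <- as.matrix(dist(x))
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[2:(n_neighbors + 1)]
    Z <- sweep(x[nb, , drop = FALSE], 2, x[i, ])
    G <- tcrossprod(Z)
    G <- G + diag(n_neighbors) * 1e-3 * sum(diag(G)) / n_neighbors
    w <- solve(G, rep(1, n_neighbors))
    W[i, nb] <- w / sum(w)
  }
  M <- crossprod(diag(n) - W)
  ev <- eigen(M, symmetric = TRUE)
  idx <- order(ev$values)[2:(k + 1)]  # drop the constant eigenvector
  ev$vectors[, idx, drop = FALSE] * sqrt(n)
}

#' Predictive manifold: a 1-D embedding as a prediction
#'
#' Reduces the (weighted) array to a single dimension, standardizes the
#' coordinate to z-scores, and flips its sign if it correlates negatively
#' with the observed target, so every manifold speaks the target's own
#' scaled language and can be scored like a prediction. The whole array is
#' used without a train/test split; the target enters only for orientation
#' and scoring.
#'
#' @param x Numeric matrix or `weighted_array`.
#' @param method Embedding method (see [embed_array()]).
#' @param y Observed target (full length).
#' @param seed Seed.
#' @param ... Passed to [embed_array()].
#' @return A `manifold_prediction`: `method`, `z` (standardized, sign-aligned
#'   vector), `accuracy` (vs `y`).
#' @export
predictive_manifold <- function(x, method, y, seed = 1L, ...) {
  emb <- embed_array(x, method = method, k = 1, seed = seed, ...)
  v <- drop(emb$coordinates)
  if (pop_sd(v) == 0) stop("zero-variance embedding")
  z <- standardize(v)
  if (cor(z, y) < 0) z <- -z
  structure(list(method = method, z = z,
                 accuracy = accuracy_block(y, z)),
            class = "manifold_prediction")
}

#' @export
print.manifold_prediction <- function(x, ...) {
  cat(sprintf("manifold_prediction [%s]: ", x$method)); print(x$accuracy)
  invisible(x)
}

#' MDS ecliptic: a plane through the 3-D MDS projection
#'
#' Uses two rather than one of the dimensions of a three-dimensional MDS
#' projection: the target is least-squares fitted on the first two MDS
#' coordinates and the fitted values, standardized, form the prediction. If
#' the two coordinates are collinear the fit falls back to the first
#' dimension alone with a warning.
#'
#' @param x Numeric matrix or `weighted_array` (n > 3).
#' @param y Observed target.
#' @param seed Seed (interface uniformity; classical MDS is deterministic).
#' @return A `manifold_prediction` with method `"mds_ecliptic"`.
#' @export
mds_ecliptic <- function(x, y, seed = 1L) {
  x <- unclass(as.matrix(x))
  if (nrow(x) <= 3) stop("need more than 3 observations")
  co <- embed_array(x, "mds", k = 3, seed = seed)$coordinates
  d1 <- co[, 1]; d2 <- co[, 2]
  if (abs(cor(d1, d2)) > 1 - 1e-10 || pop_sd(d2) == 0) {
    warning("collinear MDS coordinates; falling back to one dimension")
    fitted <- lm(y ~ d1)$fitted.values
  } else {
    fitted <- lm(y ~ d1 + d2)$fitted.values
  }
  z <- standardize(unname(fitted))
  structure(list(method = "mds_ecliptic", z = z,
                 accuracy = accuracy_block(y, z)),
            class = "manifold_prediction")
}

#' Unsupervised-OLS blend of predictive manifolds
#'
#' The meta-step of predictive unsupervised learning: ordinary least squares
#' of the target on the stacked standardized manifold vectors; the fitted
#' values, standardized, are the composite prediction. Collinear columns are
#' dropped with a warning.
#'
#' @param manifolds List of `manifold_prediction` objects (>= 2).
#' @param y Observed target.
#' @return A `manifold_prediction` with method `"unsupervised_ols"` and the
#'   blend coefficients in `$coefficients`.
#' @export
unsupervised_ols_blend <- function(manifolds, y) {
  if (length(manifolds) < 2) stop("need at least 2 manifold vectors")
  Z <- vapply(manifolds, function(m) m$z, numeric(length(y)))
  colnames(Z) <- vapply(manifolds, function(m) m$method, character(1))
  qz <- qr(cbind(1, Z))
  if (qz$rank < ncol(Z) + 1) {
    keep <- qz$pivot[seq_len(qz$rank)]
    keep <- setdiff(keep, 1) - 1
    warning(sprintf("dropping collinear manifold column(s): %s",
                    paste(setdiff(colnames(Z), colnames(Z)[keep]),
                          collapse = ", ")))
    Z <- Z[, keep, drop = FALSE]
  }
  fit <- lm(y ~ Z)
  z <- standardize(unname(fit$fitted.values))
  structure(list(method = "unsupervised_ols", z = z,
                 accuracy = accuracy_block(y, z),
                 coefficients = coef(fit)),
            class = "manifold_prediction")
}
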