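#' Emulated feature importances for a linear model
#'
#' Translates beta coefficients and p-values into the probability-vector
#' language of tree-model feature importances:
#' \deqn{f_v = \frac{|\beta_v| (1 - p_v)^\gamma}{\sum_j |\beta_j| (1 - p_j)^\gamma}}
#' The absolute beta supplies a non-negative magnitude; discounting by
#' \eqn{(1-p)^\gamma} treats statistical significance as a continuum instead
#' of star thresholds. \eqn{\gamma = 2} (the default) discounts weakly
#' significant variables more sharply; \eqn{\gamma = 1} is also available.
#'
#' @param beta Signed coefficient vector (entity/time dummies and the
#'   constant are excluded by convention; pass the 23 substantive slopes).
#' @param pvalues Matching p-values in `[0, 1]`.
#' @param gamma Discount exponent.
#' @return An `importance_vector`: named non-negative weights summing to 1,
#'   with `gamma` kept as an attribute.
#' @export
#' @examples
#' emulate_importances(c(a = 1, b = 2), c(a = 0.5, b = 0.5))  # 1/3, 2/3
emulate_importances <- function(beta, pvalues, gamma = 2) {
  if (length(beta) != length(pvalues)) stop("beta and pvalues lengths differ")
  if (any(pvalues < 0 | pvalues > 1)) stop("pvalues must lie in [0, 1]")
  raw <- abs(beta) * (1 - pvalues)^gamma
  if (sum(raw) == 0)
    stop("all-zero numerator: every |beta|(1-p)^gamma vanished")
  structure(raw / sum(raw), gamma = gamma, class = "importance_vector")
}

#' Gini coefficient of a weight vector
#'
#' With values sorted ascending,
#' \eqn{G = \frac{2 \sum_i i\, x_{(i)}}{n \sum_i x_i} - \frac{n+1}{n}}
#' (no small-sample correction); 0 for perfectly even weights,
#' \eqn{(n-1)/n} for a one-hot vector. Also returns the Lorenz-curve points
#' (cumulative population share vs cumulative weight share).
#'
#' @param v Non-negative weights with positive sum.
#' @return Numeric Gini coefficient with the Lorenz points in
#'   `attr(, "lorenz")`.
#' @export
gini_coefficient <- function(v) {
  if (any(v < 0)) stop("negative entries")
  if (sum(v) <= 0) stop("weights must have positive sum")
  x <- sort(as.numeric(v))
  n <- length(x)
  g <- (2 * sum(seq_len(n) * x)) / (n * sum(x)) - (n + 1) / n
  lorenz <- data.frame(pop_share = seq_len(n) / n,
                       weight_share = cumsum(x) / sum(x))
  structure(g, lorenz = lorenz)
}

#' Simpson's index of concentration and its reciprocal
#'
#' \eqn{\lambda = \sum_i p_i^2} on the internally normalized shares
#' (the Herfindahl-Hirschman index); \eqn{1/\lambda} is the equivalent
#' number of equally weighted components.
#'
#' @param v Non-negative weights, normalized internally to sum 1.
#' @return A `diversity_stats` list: `gini`, `simpson`, `inv_simpson`.
#' @export
simpson_index <- function(v) {
  if (any(v < 0)) stop("negative entries")
  if (sum(v) <= 0) stop("zero weight vector")
  p <- as.numeric(v) / sum(v)
  lam <- sum(p^2)
  structure(list(gini = as.numeric(gini_coefficient(v)),
                 simpson = lam, inv_simpson = 1 / lam),
            class = "diversity_stats")
}

#' @export
print.diversity_stats <- function(x, ...) {
  cat(sprintf("gini %.6f  simpson %.6f  1/simpson %.6f\n",
              x$gini, x$simpson, x$inv_simpson))
  invisible(x)
}

#' Construct / validate an importance matrix
#'
#' A features-by-models matrix whose every column is a probability vector.
#'
#' @param m Numeric matrix with feature row names and model column names.
#' @param provenance Character vector per column, `"emulated"` or `"actual"`.
#' @return An `importance_matrix`.
#' @export
importance_matrix <- function(m, provenance = rep("actual", ncol(m))) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) stop("feature row names required")
  if (any(m < 0)) stop("negative importances")
  cs <- colSums(m)
  if (any(abs(cs - 1) > 1e-9))
    stop("every column must sum to 1 (within 1e-9)")
  if (length(provenance) != ncol(m)) stop("one provenance tag per column")
  structure(m, provenance = provenance, class = c("importance_matrix", "matrix"))
}

#' Concatenate emulated (L) and actual (M) importances into F = (L | M)
#'
#' Column-binds the linear models' emulated importances and the machine
#' learning models' actual importances into the grand feature-by-model
#' matrix, linear columns first. Row (feature) labels must agree exactly, in
#' order.
#'
#' @param L `importance_matrix` of emulated importances (features x k).
#' @param M `importance_matrix` of actual importances (features x m).
#' @return The combined `importance_matrix` F (features x (k+m)).
#' @export
concat_importance_matrix <- function(L, M) {
  if (!identical(rownames(L), rownames(M))) {
    off <- union(setdiff(rownames(L), rownames(M)),
                 setdiff(rownames(M), rownames(L)))
    if (length(off) == 0) off <- rownames(L)[rownames(L) != rownames(M)]
    stop(sprintf("row label mismatch between L and M: %s",
                 paste(off, collapse = ", ")))
  }
  importance_matrix(cbind(unclass(L), unclass(M)),
                    provenance = c(attr(L, "provenance") %||%
                                     rep("emulated", ncol(L)),
                                   attr(M, "provenance") %||%
                                     rep("actual", ncol(M))))
}

#' Aggregate importances across models: V = F W
#'
#' The matrix-vector product of the grand importance matrix with a
#' probability vector of model weights (typically the stacking blender's
#' importances) yields one aggregated importance per feature; since F is
#' column-stochastic and W is stochastic, V sums to 1 by construction.
#'
#' @param F_mat An `importance_matrix` (features x models).
#' @param W Non-negative model weights summing to 1, length `ncol(F_mat)`.
#' @return An `importance_vector` V.
#' @export
aggregate_importances <- function(F_mat, W) {
  if (length(W) != ncol(F_mat))
    stop("non-conformable: length(W) must equal ncol(F)")
  if (any(W < 0)) stop("negative model weights")
  if (abs(sum(W) - 1) > 1e-9) stop("model weights must sum to 1")
  v <- drop(unclass(F_mat) %*% as.numeric(W))
  structure(setNames(v, rownames(F_mat)), class = "importance_vector")
}

#' @export
print.importance_vector <- function(x, ...) {
  v <- unclass(x)
  attributes(v) <- list(names = names(v))
  cat(sprintf("importance_vector (%d features, sum %.6f)\n",
              length(v), sum(v)))
  print(round(sort(v, decreasing = TRUE)[seq_len(min(5, length(v)))], 4))
  invisible(x)
}

#' Diversity report for importance columns
#'
#' Gini, Simpson and reciprocal-Simpson per column of an importance matrix
#' (the layout of the published diversity tables).
#'
#' @param F_mat An `importance_matrix` (or plain matrix of importance
#'   columns).
#' @param path Optional CSV path.
#' @return data.frame with one column per model and rows
#'   `gini`, `simpson`, `inv_simpson`.
#' @export
export_diversity_table <- function(F_mat, path = NULL) {
  stats <- apply(unclass(F_mat), 2, function(col) {
    s <- simpson_index(col)
    c(gini = s$gini, simpson = s$simpson, inv_simpson = s$inv_simpson)
  })
  out <- data.frame(index = rownames(stats), stats, check.names = FALSE)
  if (!is.null(path)) {
    write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
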