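#' PCA composite index for a variable group
#'
#' Decomposes the economic (11-variable) or health-based (12-variable) slice
#' of the posterior, accuracy-weighted array into its first principal
#' component at observation level, then averages by country. Because PCA is
#' sign-indeterminate, the index is oriented so that it correlates
#' positively with an anchor column: `real_gdp_pc` for the economic group
#' (higher index = more prosperous) and `exposure` for the health group.
#'
#' @param weighted_array Numeric matrix (observations x features) with the
#'   group's columns present; typically a `weighted_array`.
#' @param group `"economic"` or `"health"`.
#' @param entities Entity label per row.
#' @param group_map Feature-to-group map.
#' @param anchor Orientation anchor column; default depends on `group`.
#' @param aggregate_first If `TRUE`, aggregate to country means before PCA
#'   instead of after (the alternative ordering, off by default).
#' @return A `composite_index`: `group`, `variables`, named per-country
#'   `values`, `orientation` note.
#' @export
composite_index <- function(weighted_array, group = c("economic", "health"),
                            entities, group_map = pm25_group_map(),
                            anchor = NULL, aggregate_first = FALSE) {
  group <- match.arg(group)
  x <- unclass(as.matrix(weighted_array))
  vars <- names(group_map)[group_map == group]
  missing_vars <- setdiff(vars, colnames(x))
  if (length(missing_vars) > 0)
    stop(sprintf("group variables absent from array: %s",
                 paste(missing_vars, collapse = ", ")))
  slice <- x[, vars, drop = FALSE]
  if (aggregate_first) {
    slice <- aggregate_by_country(slice, entities)
    entities <- rownames(slice)
  }
  if (all(apply(slice, 2, pop_sd) == 0))
    stop("group slice is constant; no principal component exists")
  anchor <- anchor %||% if (group == "economic") "real_gdp_pc" else "exposure"
  pc <- prcomp(slice, center = TRUE, scale. = FALSE)
  scores <- pc$x[, 1]
  if (anchor %in% colnames(slice) && pop_sd(slice[, anchor]) > 0 &&
      cor(scores, slice[, anchor]) < 0)
    scores <- -scores
  values <- if (aggregate_first) setNames(scores, entities) else
    drop(aggregate_by_country(matrix(scores), entities))
  structure(list(group = group, variables = vars, values = values,
                 orientation = sprintf("positively correlated with %s",
                                       anchor),
                 loadings = pc$rotation[, 1]),
            class = "composite_index")
}

#' @export
print.composite_index <- function(x, ...) {
  cat(sprintf("composite_index [%s]: %d countries, oriented %s\n",
              x$group, length(x$values), x$orientation))
  print(round(sort(x$values), 3))
  invisible(x)
}

#' Environmental Kuznets curve fits
#'
#' Least-squares polynomial fits of degree 1 through 4 of country-level
#' PM2.5 mortality on a composite index, plus the unweighted pointwise
#' average of the degree-2, 3 and 4 fitted curves on a 200-point grid
#' spanning the index range. The three canonical Kuznets shapes correspond
#' to degree 1 (monotone), 2 (inverted U) and 3 (N-shaped); the averaged
#' higher-degree curve summarizes them.
#'
#' @param index Composite index values (x-axis), one per country, or a
#'   `composite_index`.
#' @param mortality Country-level mean scaled PM2.5 mortality (y-axis).
#' @return A `kuznets_curve`: `x`, `y`, `fits` (list of degree-d coefficient
#'   vectors, intercept first), `grid`, `curves` (per-degree fitted values
#'   on the grid), `average_curve`, `residual_ss` per degree.
#' @export
kuznets_curves <- function(index, mortality) {
  if (inherits(index, "composite_index")) index <- index$values
  x <- as.numeric(index); y <- as.numeric(mortality)
  if (length(x) != length(y)) stop("index and mortality lengths differ")
  if (length(x) < 5) stop("need at least 5 points for degree-4 fits")
  assert_finite(x, "index"); assert_finite(y, "mortality")
  grid <- seq(min(x), max(x), length.out = 200)
  fits <- list(); curves <- list(); rss <- numeric(4)
  for (d in 1:4) {
    fit <- lm(y ~ poly(x, d, raw = TRUE))
    cf <- unname(coef(fit))
    fits[[d]] <- cf
    curves[[d]] <- drop(outer(grid, 0:d, "^") %*% cf)
    rss[d] <- sum(fit$residuals^2)
  }
  names(fits) <- names(curves) <- paste0("degree_", 1:4)
  structure(list(x = x, y = y, fits = fits, grid = grid, curves = curves,
                 average_curve = (curves[[2]] + curves[[3]] + curves[[4]]) / 3,
                 residual_ss = setNames(rss, names(fits))),
            class = "kuznets_curve")
}

#' @export
print.kuznets_curve <- function(x, ...) {
  cat(sprintf("kuznets_curve: %d points; residual SS by degree: %s\n",
              length(x$x),
              paste(sprintf("%.3f", x$residual_ss), collapse = ", ")))
  invisible(x)
}

#' One-standard-deviation covariance ellipses per cluster
#'
#' For each cluster of 2-D points: center = mean, axes = square roots of the
#' covariance eigenvalues, tilt = angle of the principal eigenvector.
#' Degenerate clusters (fewer than 3 points, or zero variance) receive a
#' minimal-width fallback ellipse (2% of the global coordinate range) and
#' are flagged.
#'
#' @param points Numeric n x 2 matrix.
#' @param labels Cluster label per row.
#' @return data.frame: one row per cluster with `label`, `n`, `center_x`,
#'   `center_y`, `axis_major`, `axis_minor`, `tilt` (radians), `degenerate`.
#' @export
cluster_ellipse <- function(points, labels) {
  points <- as.matrix(points)
  if (ncol(points) != 2) stop("points must be 2-D")
  if (length(labels) != nrow(points)) stop("one label per point required")
  if (length(labels) == 0) stop("empty label set")
  eps <- 0.02 * max(apply(points, 2, function(c) diff(range(c))), 1e-8)
  out <- lapply(unique(labels), function(lb) {
    p <- points[labels == lb, , drop = FALSE]
    n <- nrow(p)
    ctr <- colMeans(p)
    if (n < 3 || all(apply(p, 2, pop_sd) == 0)) {
      return(data.frame(label = lb, n = n, center_x = ctr[1],
                        center_y = ctr[2], axis_major = eps,
                        axis_minor = eps, tilt = 0, degenerate = TRUE))
    }
    ev <- eigen(stats::cov(p), symmetric = TRUE)
    ax <- sqrt(pmax(ev$values, 0))
    degen <- ax[2] == 0
    if (degen) ax[2] <- eps
    data.frame(label = lb, n = n, center_x = ctr[1], center_y = ctr[2],
               axis_major = ax[1], axis_minor = ax[2],
               tilt = atan2(ev$vectors[2, 1], ev$vectors[1, 1]),
               degenerate = degen)
  })
  do.call(rbind, out)
}

#' Sundew plot data: two models against the ground truth
#'
#' Per observation: both predictions and their absolute vertical distances
#' from the observed value, the ingredients of the sundew comparison plot.
#'
#' @param obs Observed values.
#' @param pred_a,pred_b Competing predictions.
#' @return data.frame with `obs`, `pred_a`, `pred_b`, `dist_a`, `dist_b`.
#' @export
sundew_plot_data <- function(obs, pred_a, pred_b) {
  if (length(pred_a) != length(obs) || length(pred_b) != length(obs))
    stop("length mismatch")
  data.frame(obs = obs, pred_a = pred_a, pred_b = pred_b,
             dist_a = abs(pred_a - obs), dist_b = abs(pred_b - obs))
}

#' Export a Kuznets table (country, index, mortality)
#'
#' @param index A `composite_index` (or named vector).
#' @param mortality Named per-country mortality vector (aligned by name when
#'   both are named).
#' @param path Optional CSV path.
#' @export
export_kuznets_table <- function(index, mortality, path = NULL) {
  vals <- if (inherits(index, "composite_index")) index$values else index
  if (!is.null(names(vals)) && !is.null(names(mortality)))
    mortality <- mortality[names(vals)]
  out <- data.frame(country = names(vals) %||% seq_along(vals),
                    index = as.numeric(vals),
                    mortality = as.numeric(mortality))
  if (!is.null(path)) {
    write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
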