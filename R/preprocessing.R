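#' Random train/test split of panel rows
#'
#' Plain uniform shuffle (no stratification by entity or year), reserving
#' `floor(n * test_fraction)` rows for testing; with the default quarter on
#' 297 rows this yields the 223/74 partition the pipeline is built around.
#'
#' @param panel A `panel_dataset`.
#' @param test_fraction Fraction of rows held out, in (0, 1).
#' @param seed Integer seed; the split is reproducible.
#' @return List with sorted integer vectors `train_idx` and `test_idx`.
#' @export
split_panel <- function(panel, test_fraction = 0.25, seed = 1L) {
  stopifnot(inherits(panel, "panel_dataset"))
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie strictly between 0 and 1")
  n <- length(panel$y)
  n_test <- floor(n * test_fraction)
  if (n_test < 1) stop("test_fraction leaves no test rows")
  set.seed(seed)
  test_idx <- sort(sample.int(n, n_test))
  list(train_idx = setdiff(seq_len(n), test_idx), test_idx = test_idx)
}

#' Leakage-safe standard scaling
#'
#' Standardizes both partitions with the training partition's parameters
#' only: \eqn{z = (x - \mu_{train}) / \sigma_{train}}, where \eqn{\sigma}
#' uses the population (1/n) convention.
#'
#' @param train Numeric matrix (or vector) of training rows.
#' @param test Numeric matrix (or vector) of test rows, same columns.
#' @return List with `train`, `test` (standardized), `center`, `scale`.
#' @export
standard_scale <- function(train, test = NULL) {
  train <- as.matrix(train)
  mu <- colMeans(train)
  sigma <- apply(train, 2, pop_sd)
  zero <- sigma == 0
  if (any(zero))
    stop(sprintf("zero-variance training column(s): %s",
                 paste(colnames(train)[zero] %||% which(zero), collapse = ", ")))
  tr <- sweep(sweep(train, 2, mu), 2, sigma, "/")
  te <- if (!is.null(test)) {
    test <- as.matrix(test)
    sweep(sweep(test, 2, mu), 2, sigma, "/")
  }
  list(train = tr, test = te, center = mu, scale = sigma)
}

#' Split and scale a panel for the supervised stage
#'
#' Applies [split_panel()] and [standard_scale()], and additionally carries a
#' full-data standardized copy of the features and target for the
#' unsupervised stages (which use all rows without a split; that copy is
#' scaled on full-data parameters since no holdout exists there). The
#' endogenous welfare variable, if present, is scaled with training
#' parameters like the features.
#'
#' @param panel A complete (fully observed) `panel_dataset`.
#' @param test_fraction,seed Passed to [split_panel()].
#' @return A `scaled_split` with `train_idx`, `test_idx`, `scaler`
#'   (per-feature center/scale incl. the target), `X_train`, `X_test`,
#'   `y_train`, `y_test`, `welfare_train`, `welfare_test`,
#'   `full_scaled_X`, `full_scaled_y`, plus entity/year bookkeeping.
#' @export
scaled_split <- function(panel, test_fraction = 0.25, seed = 1L) {
  stopifnot(inherits(panel, "panel_dataset"))
  if (any(panel$missing_mask) || anyNA(panel$X))
    stop("panel has missing cells; impute before scaling")
  idx <- split_panel(panel, test_fraction, seed)
  sx <- standard_scale(panel$X[idx$train_idx, , drop = FALSE],
                       panel$X[idx$test_idx, , drop = FALSE])
  sy <- standard_scale(panel$y[idx$train_idx], panel$y[idx$test_idx])
  w_tr <- w_te <- NULL
  if (!is.null(panel$welfare)) {
    sw <- standard_scale(panel$welfare[idx$train_idx],
                         panel$welfare[idx$test_idx])
    w_tr <- drop(sw$train); w_te <- drop(sw$test)
  }
  full_x <- standard_scale(panel$X)$train
  full_y <- drop(standard_scale(panel$y)$train)
  structure(list(
    train_idx = idx$train_idx, test_idx = idx$test_idx,
    scaler = list(center = sx$center, scale = sx$scale,
                  y_center = sy$center[[1]], y_scale = sy$scale[[1]]),
    X_train = sx$train, X_test = sx$test,
    y_train = drop(sy$train), y_test = drop(sy$test),
    welfare_train = w_tr, welfare_test = w_te,
    full_scaled_X = full_x, full_scaled_y = full_y,
    entity = panel$entity, year = panel$year,
    entity_train = panel$entity[idx$train_idx],
    entity_test = panel$entity[idx$test_idx],
    year_train = panel$year[idx$train_idx],
    year_test = panel$year[idx$test_idx]),
    class = "scaled_split")
}

#' @export
print.scaled_split <- function(x, ...) {
  cat(sprintf("scaled_split: %d train / %d test rows, %d features\n",
              nrow(x$X_train), nrow(x$X_test), ncol(x$X_train)))
  invisible(x)
}

#' Serialize split indices and scaler parameters to JSON
#'
#' Enough to rerun the exact partition and transformation.
#' @param split A `scaled_split`.
#' @param path Optional file; if `NULL` the JSON string is returned.
#' @export
scaled_split_json <- function(split, path = NULL) {
  js <- jsonlite::toJSON(list(train_idx = split$train_idx,
                              test_idx = split$test_idx,
                              scaler = split$scaler),
                         auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Country-level mean aggregation
#'
#' Collapses a row-per-observation matrix to one row per entity (arithmetic
#' mean of that entity's rows), preserving first-appearance entity order.
#' On the default panel this turns the 297 x 23 scaled array into the
#' 27 x 23 country aggregate used for country-level clustering and the
#' Kuznets curves.
#'
#' @param X Numeric matrix, one row per observation.
#' @param entities Entity label per row (no NAs).
#' @return Matrix with one named row per entity.
#' @export
aggregate_by_country <- function(X, entities) {
  X <- as.matrix(X)
  if (length(entities) != nrow(X)) stop("one entity label per row required")
  if (anyNA(entities)) stop("unknown (NA) entity labels")
  lev <- unique(entities)
  out <- rowsum(X, factor(entities, levels = lev)) /
    as.vector(table(factor(entities, levels = lev)))
  rownames(out) <- lev
  out
}
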