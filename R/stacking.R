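#' Assemble the level-0 prediction matrix
#'
#' Stacking generalization treats every fitted model as an independent
#' variable: column `m` of the level-0 matrix holds model `m`'s predictions.
#' Train and test blocks must come from the same split.
#'
#' @param fits List of `linear_fit` / `ensemble_fit` objects (column order
#'   preserved).
#' @return A `level0_matrix`: `train` (n_train x m), `test` (n_test x m),
#'   `model_ids`.
#' @export
assemble_level0 <- function(fits) {
  if (length(fits) < 1) stop("no fits supplied")
  for (f in fits) {
    if (is.null(f$train_pred) || is.null(f$test_pred))
      stop(sprintf("fit '%s' lacks train or test predictions",
                   f$model_id %||% "?"))
  }
  n_tr <- vapply(fits, function(f) length(f$train_pred), integer(1))
  n_te <- vapply(fits, function(f) length(f$test_pred), integer(1))
  if (length(unique(n_tr)) != 1 || length(unique(n_te)) != 1)
    stop("fits disagree on split sizes; were they fitted on the same split?")
  ids <- unname(vapply(fits, function(f) f$model_id, character(1)))
  tr <- vapply(fits, function(f) as.numeric(f$train_pred), numeric(n_tr[1]))
  te <- vapply(fits, function(f) as.numeric(f$test_pred), numeric(n_te[1]))
  colnames(tr) <- colnames(te) <- ids
  assert_finite(tr, "level-0 train predictions")
  assert_finite(te, "level-0 test predictions")
  structure(list(train = tr, test = te, model_ids = ids),
            class = "level0_matrix")
}

#' Fit the level-1 stacking blender
#'
#' A tree ensemble (extra trees by default, random forest as the
#' alternative) trained on the level-0 training predictions. Its impurity
#' feature importances, one per stacked model, form the model-weight vector
#' W used to aggregate feature importances across models. The blender trains
#' on in-sample level-0 training predictions (the described protocol;
#' optimistic by construction). `mode = "out_of_fold"` additionally reports
#' the blender's train-side meta-predictions out-of-fold (5-fold) so train
#' accuracy is honest; W and test predictions always come from the full fit.
#'
#' @param level0 A `level0_matrix`.
#' @param y_train Training target.
#' @param blender_id `"extra_trees"` or `"random_forest"`.
#' @param y_test Optional test target for test-side accuracy.
#' @param seed Seed.
#' @param n_trees Trees in the blender (500, unbounded depth).
#' @param mode `"insample"` (default) or `"out_of_fold"`.
#' @return A `blender_fit`: `blender_id`, `W` (probability vector over
#'   models), `train_pred`, `test_pred`, `accuracy`, `diversity`
#'   (diversity stats of W).
#' @export
fit_blender <- function(level0, y_train, blender_id = c("extra_trees",
                                                        "random_forest"),
                        y_test = NULL, seed = 1L, n_trees = 500,
                        mode = c("insample", "out_of_fold")) {
  stopifnot(inherits(level0, "level0_matrix"))
  blender_id <- match.arg(blender_id)
  mode <- match.arg(mode)
  if (ncol(level0$train) < 2) stop("need at least 2 level-0 columns")
  if (length(y_train) != nrow(level0$train))
    stop("y_train length does not match level-0 rows")
  train_fit <- function(X, y) {
    if (blender_id == "extra_trees") {
      df <- data.frame(X, check.names = FALSE); df$.y <- y
      fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                            num.trees = n_trees, mtry = ncol(X),
                            splitrule = "extratrees", num.random.splits = 1,
                            importance = "impurity", seed = seed,
                            num.threads = 1)
      list(predict = function(newx)
        predict(fit, data.frame(newx, check.names = FALSE),
                num.threads = 1)$predictions,
        importances = fit$variable.importance)
    } else {
      set.seed(seed)
      fit <- randomForest::randomForest(X, y, ntree = n_trees,
                                        mtry = ncol(X))
      list(predict = function(newx) unname(predict(fit, newx)),
           importances = fit$importance[, "IncNodePurity"])
    }
  }
  full <- train_fit(level0$train, y_train)
  W <- full$importances
  W[W < 0] <- 0
  if (sum(W) == 0) stop("blender produced all-zero importances")
  W <- W / sum(W)
  tr_pred <- full$predict(level0$train)
  if (mode == "out_of_fold") {
    set.seed(seed)
    fold_of <- sample(rep_len(1:5, nrow(level0$train)))
    tr_pred <- numeric(nrow(level0$train))
    for (k in 1:5) {
      tr <- fold_of != k
      fk <- train_fit(level0$train[tr, , drop = FALSE], y_train[tr])
      tr_pred[!tr] <- fk$predict(level0$train[!tr, , drop = FALSE])
    }
  }
  te_pred <- full$predict(level0$test)
  acc <- list(train = accuracy_block(y_train, tr_pred),
              test = if (!is.null(y_test)) accuracy_block(y_test, te_pred))
  structure(list(blender_id = blender_id, W = W, mode = mode,
                 train_pred = tr_pred, test_pred = te_pred,
                 accuracy = acc, diversity = blender_diversity(W),
                 model_id = paste0("stack_", blender_id), seed = seed),
            class = "blender_fit")
}

#' @export
print.blender_fit <- function(x, ...) {
  cat(sprintf("blender_fit [%s, %s]: %d stacked models\n",
              x$blender_id, x$mode, length(x$W)))
  cat("  W diversity: "); print(x$diversity)
  cat("  train: "); print(x$accuracy$train)
  if (!is.null(x$accuracy$test)) { cat("  test:  "); print(x$accuracy$test) }
  invisible(x)
}

#' Diversity of the blender's model weights
#'
#' Gini/Simpson/reciprocal-Simpson of W; the reciprocal reads as the
#' equivalent number of equally weighted models the blender consulted.
#'
#' @param W Non-negative model weights.
#' @return A `diversity_stats` list.
#' @export
blender_diversity <- function(W) simpson_index(W)
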