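# The six tree-ensemble regressors. Backends: randomForest (random forest),
# ranger with the extra-trees split rule (extremely randomized trees),
# xgboost (depth-wise gradient boosting, and a histogram/leaf-wise variant in
# the LightGBM style), plus two boosting algorithms written here because no
# installed package provides them: AdaBoost.R2 over decision stumps and
# classic least-squares gradient boosting over shallow CART trees.

ENSEMBLE_IDS <- c("random_forest", "extra_trees", "adaboost",
                  "gradient_boosting", "xgboost", "lightgbm")

#' @noRd
rpart_ctrl <- function(maxdepth) {
  rpart::rpart.control(maxdepth = maxdepth, cp = 0, xval = 0,
                       minsplit = 10, minbucket = 5,
                       maxsurrogate = 0, usesurrogate = 0)
}

# rpart variable.importance as a full named vector over all features.
#' @noRd
rpart_importance <- function(tree, feats) {
  imp <- setNames(rep(0, length(feats)), feats)
  vi <- tree$variable.importance
  if (!is.null(vi)) imp[names(vi)] <- vi
  imp
}

# AdaBoost.R2 (Drucker 1997) with linear loss and weighted-median prediction.
#' @noRd
fit_adaboost_r2 <- function(X, y, n_estimators = 300, learning_rate = 0.1,
                            maxdepth = 1) {
  df <- data.frame(X, check.names = FALSE)
  n <- nrow(df)
  w <- rep(1 / n, n)
  trees <- list(); betas <- numeric(0)
  imp <- setNames(rep(0, ncol(X)), colnames(X))
  for (m in seq_len(n_estimators)) {
    tree <- rpart::rpart(y ~ ., data = cbind(df, y = y), weights = w * n,
                         control = rpart_ctrl(maxdepth))
    pred <- predict(tree, df)
    err <- abs(pred - y)
    emax <- max(err)
    if (emax == 0) { trees[[m]] <- tree; betas[m] <- 1e-10; break }
    loss <- err / emax
    lbar <- sum(w * loss)
    if (lbar >= 0.5) { if (m == 1) { trees[[m]] <- tree; betas[m] <- 1 }; break }
    beta <- lbar / (1 - lbar)
    trees[[m]] <- tree
    betas[m] <- beta
    w <- w * beta^(learning_rate * (1 - loss))
    w <- w / sum(w)
    imp <- imp + log(1 / beta) * rpart_importance(tree, colnames(X))
  }
  structure(list(trees = trees, betas = betas, importances = imp,
                 feats = colnames(X)),
            class = "adaboost_r2")
}

#' @noRd
predict.adaboost_r2 <- function(object, newdata, ...) {
  df <- data.frame(newdata, check.names = FALSE)
  P <- vapply(object$trees, function(tr) predict(tr, df),
              numeric(nrow(df)))
  if (is.null(dim(P))) P <- matrix(P, nrow = nrow(df))
  wts <- log(1 / object$betas)
  if (all(wts <= 0)) wts <- rep(1, length(wts))
  apply(P, 1, function(p) {
    o <- order(p)
    cw <- cumsum(wts[o])
    p[o][which(cw >= 0.5 * cw[length(cw)])[1]]
  })
}

# Least-squares gradient boosting (Friedman) over CART trees.
#' @noRd
fit_gb_trees <- function(X, y, n_estimators = 500, learning_rate = 0.1,
                         max_depth = 3) {
  df <- data.frame(X, check.names = FALSE)
  f0 <- mean(y)
  fit <- rep(f0, length(y))
  trees <- vector("list", n_estimators)
  imp <- setNames(rep(0, ncol(X)), colnames(X))
  for (m in seq_len(n_estimators)) {
    r <- y - fit
    tree <- rpart::rpart(r ~ ., data = cbind(df, r = r),
                         control = rpart_ctrl(max_depth))
    trees[[m]] <- tree
    fit <- fit + learning_rate * predict(tree, df)
    imp <- imp + rpart_importance(tree, colnames(X))
  }
  structure(list(trees = trees, f0 = f0, lr = learning_rate,
                 importances = imp, feats = colnames(X)),
            class = "gb_trees")
}

#' @noRd
predict.gb_trees <- function(object, newdata, ...) {
  df <- data.frame(newdata, check.names = FALSE)
  out <- rep(object$f0, nrow(df))
  for (tr in object$trees) out <- out + object$lr * predict(tr, df)
  out
}

# One fit + prediction pass used by both grid search and fit_ensemble.
#' @noRd
ensemble_engine <- function(model_id, params, X, y, seed) {
  p <- ncol(X)
  set.seed(seed)
  switch(model_id,
    random_forest = {
      depth <- params$max_depth
      fit <- randomForest::randomForest(
        X, y, ntree = params$n_trees %||% 500,
        mtry = params$mtry %||% max(1, floor(p / 3)),
        maxnodes = if (!is.null(depth)) 2^depth)
      list(fit = fit,
           predict = function(newx) unname(predict(fit, newx)),
           importances = fit$importance[, "IncNodePurity"])
    },
    extra_trees = {
      df <- data.frame(X, check.names = FALSE); df$.y <- y
      fit <- ranger::ranger(
        dependent.variable.name = ".y", data = df,
        num.trees = params$n_trees %||% 500,
        mtry = params$mtry %||% max(1, floor(p / 3)),
        max.depth = params$max_depth %||% 0,
        splitrule = "extratrees", num.random.splits = 1,
        importance = "impurity", seed = seed, num.threads = 1)
      list(fit = fit,
           predict = function(newx)
             predict(fit, data.frame(newx, check.names = FALSE),
                     num.threads = 1)$predictions,
           importances = fit$variable.importance)
    },
    adaboost = {
      fit <- fit_adaboost_r2(X, y,
                             n_estimators = params$n_estimators %||% 300,
                             learning_rate = params$learning_rate %||% 0.1)
      list(fit = fit,
           predict = function(newx) predict.adaboost_r2(fit, newx),
           importances = fit$importances)
    },
    gradient_boosting = {
      fit <- fit_gb_trees(X, y,
                          n_estimators = params$n_estimators %||% 500,
                          learning_rate = params$learning_rate %||% 0.1,
                          max_depth = params$max_depth %||% 3)
      list(fit = fit,
           predict = function(newx) predict.gb_trees(fit, newx),
           importances = fit$importances)
    },
    xgboost = {
      fit <- xgboost::xgboost(
        X, y, objective = "reg:squarederror",
        nrounds = params$n_estimators %||% 500,
        learning_rate = params$learning_rate %||% 0.1,
        max_depth = params$max_depth %||% 3,
        nthreads = 1, seed = seed)
      list(fit = fit,
           predict = function(newx) predict(fit, newx),
           importances = xgb_gain(fit, colnames(X)))
    },
    lightgbm = {
      # histogram-based, leaf-wise booster (the LightGBM growth strategy)
      fit <- xgboost::xgboost(
        X, y, objective = "reg:squarederror",
        nrounds = params$n_estimators %||% 500,
        learning_rate = params$learning_rate %||% 0.1,
        tree_method = "hist", grow_policy = "lossguide",
        max_leaves = params$max_leaves %||% 31, max_depth = 0,
        nthreads = 1, seed = seed)
      list(fit = fit,
           predict = function(newx) predict(fit, newx),
           importances = xgb_gain(fit, colnames(X)))
    },
    stop(sprintf("unknown model_id '%s'; valid ids: %s", model_id,
                 paste(ENSEMBLE_IDS, collapse = ", ")))
  )
}

#' @noRd
xgb_gain <- function(fit, feats) {
  imp <- setNames(rep(0, length(feats)), feats)
  tab <- xgboost::xgb.importance(model = fit)
  imp[tab$Feature] <- tab$Gain
  imp
}

#' Exhaustive cross-validated grid search
#'
#' Evaluates every hyperparameter combination by K-fold cross-validation on
#' the training rows and selects the combination minimizing mean CV RMSE;
#' ties are broken by first occurrence in grid order (rows of
#' `expand.grid(grid)`).
#'
#' @param model_id One of the six ensemble ids.
#' @param grid Named list of parameter value vectors.
#' @param x,y Training features (matrix) and target.
#' @param folds Number of CV folds (>= 2).
#' @param seed Seed controlling fold assignment and model randomness.
#' @return List with `best_params` (named list) and the full `cv_table`.
#' @export
grid_search_cv <- function(model_id, grid, x, y, folds = 5, seed = 1L) {
  if (!model_id %in% ENSEMBLE_IDS)
    stop(sprintf("unknown model_id '%s'; valid ids: %s", model_id,
                 paste(ENSEMBLE_IDS, collapse = ", ")))
  if (length(grid) == 0) stop("empty grid")
  if (folds < 2) stop("folds must be >= 2")
  n <- length(y)
  if (folds > n) stop("more folds than training rows")
  combos <- expand.grid(grid, stringsAsFactors = FALSE)
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(folds), n))
  rmse <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    params <- lapply(combos[i, , drop = FALSE], function(v) {
      v <- v[[1]]
      if (is.na(v)) NULL else v
    })
    errs <- vapply(seq_len(folds), function(k) {
      tr <- fold_of != k
      eng <- ensemble_engine(model_id, params, x[tr, , drop = FALSE], y[tr],
                             seed)
      pred <- eng$predict(x[!tr, , drop = FALSE])
      sqrt(mean((pred - y[!tr])^2))
    }, numeric(1))
    rmse[i] <- mean(errs)
  }
  best <- which.min(rmse)  # which.min takes the first minimum: grid-order ties
  best_params <- lapply(combos[best, , drop = FALSE], function(v) {
    v <- v[[1]]
    if (is.na(v)) NULL else v
  })
  best_params <- best_params[!vapply(best_params, is.null, logical(1))]
  list(best_params = best_params,
       cv_table = cbind(combos, cv_rmse = rmse))
}

#' Default hyperparameter grids
#'
#' Forests and extra trees search maximum depth and feature-subset size at
#' 500 trees; AdaBoost searches learning rate and estimator count; the
#' gradient-boosting family searches learning rate, depth (leaves for the
#' histogram booster) and estimator count.
#'
#' @param model_id One of the six ensemble ids.
#' @param p Number of features (for the mtry candidates).
#' @return Named list of value vectors (NA encodes "unbounded"/default).
#' @export
default_grid <- function(model_id, p = 23) {
  mtry <- unique(pmax(1, c(floor(sqrt(p)), floor(p / 3), p)))
  switch(model_id,
    random_forest = ,
    extra_trees = list(max_depth = c(3, 5, 10, NA), mtry = mtry,
                       n_trees = 500),
    adaboost = list(learning_rate = c(0.05, 0.1, 0.5),
                    n_estimators = c(100, 300)),
    gradient_boosting = ,
    xgboost = list(learning_rate = c(0.05, 0.1), max_depth = c(2, 3, 4),
                   n_estimators = c(200, 500)),
    lightgbm = list(learning_rate = c(0.05, 0.1), max_leaves = c(7, 15, 31),
                    n_estimators = c(200, 500)),
    stop(sprintf("unknown model_id '%s'", model_id)))
}

#' Fit a tree-ensemble regressor
#'
#' Trains on the scaled training partition only, predicts both partitions,
#' and extracts impurity-based feature importances, renormalized defensively
#' to sum to exactly 1.
#'
#' @param model_id One of `random_forest`, `extra_trees`, `adaboost`,
#'   `gradient_boosting`, `xgboost`, `lightgbm`.
#' @param split A `scaled_split`.
#' @param params Named list of hyperparameters (e.g. from
#'   [grid_search_cv()]); unset entries use per-model defaults.
#' @param seed Seed, fixed to 1 across the pipeline for reproducibility.
#' @return An `ensemble_fit`: `model_id`, `best_params`, `importances`
#'   (length-23 probability vector), `train_pred`, `test_pred`, `accuracy`,
#'   `seed`.
#' @export
fit_ensemble <- function(model_id, split, params = list(), seed = 1L) {
  stopifnot(inherits(split, "scaled_split"))
  eng <- ensemble_engine(model_id, params, split$X_train, split$y_train, seed)
  tr <- eng$predict(split$X_train)
  te <- eng$predict(split$X_test)
  imp <- eng$importances
  imp[!is.finite(imp) | imp < 0] <- 0
  if (sum(imp) == 0) stop("all importances zero")
  imp <- imp / sum(imp)
  structure(list(model_id = model_id, best_params = params,
                 importances = imp, train_pred = tr, test_pred = te,
                 accuracy = list(train = accuracy_block(split$y_train, tr),
                                 test = accuracy_block(split$y_test, te)),
                 seed = seed, engine = eng),
            class = "ensemble_fit")
}

#' @export
print.ensemble_fit <- function(x, ...) {
  cat(sprintf("ensemble_fit [%s]\n", x$model_id))
  cat("  train: "); print(x$accuracy$train)
  cat("  test:  "); print(x$accuracy$test)
  top <- sort(x$importances, decreasing = TRUE)[1:3]
  cat(sprintf("  top importances: %s\n",
              paste(sprintf("%s %.3f", names(top), top), collapse = ", ")))
  invisible(x)
}

#' Export fitted importances as a feature-by-model table
#'
#' @param fits List of `ensemble_fit` and/or importance vectors.
#' @param path Optional CSV path.
#' @export
export_importance_table <- function(fits, path = NULL) {
  cols <- lapply(fits, function(f)
    if (inherits(f, "ensemble_fit")) f$importances else f)
  ids <- vapply(fits, function(f)
    if (inherits(f, "ensemble_fit")) f$model_id else "importance", character(1))
  out <- data.frame(variable = names(cols[[1]]),
                    setNames(as.data.frame(cols), make.unique(ids)))
  if (!is.null(path)) {
    write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
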