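#' Four-statistic accuracy block
#'
#' Computes the accuracy summary used for every model and partition:
#' root mean squared error, coefficient of determination
#' \eqn{r^2 = 1 - SSE/SST}, mean bias error, and Willmott's index of
#' agreement
#' \eqn{1 - \sum(p-o)^2 / \sum(|p-\bar o| + |o-\bar o|)^2} (bounded in
#' `[0, 1]`, 1 meaning complete agreement).
#'
#' @param obs Observed values.
#' @param pred Predicted values (same length, n >= 2).
#' @return An `accuracy_block` list: `rmse`, `r2`, `mbe`, `wioa`. A constant
#'   observation vector leaves `r2` as `NA` with a warning.
#' @export
#' @examples
#' accuracy_block(c(1, 2, 3), c(1.1, 2.1, 3.1))
accuracy_block <- function(obs, pred) {
  if (length(obs) != length(pred)) stop("obs and pred lengths differ")
  if (length(obs) < 2) stop("need at least 2 observations")
  assert_finite(obs, "obs"); assert_finite(pred, "pred")
  e <- pred - obs
  sst <- sum((obs - mean(obs))^2)
  r2 <- if (sst == 0) {
    warning("constant observation vector: r2 undefined")
    NA_real_
  } else 1 - sum(e^2) / sst
  denom <- sum((abs(pred - mean(obs)) + abs(obs - mean(obs)))^2)
  wioa <- if (denom == 0) 1 else 1 - sum(e^2) / denom
  structure(list(rmse = sqrt(mean(e^2)), r2 = r2, mbe = mean(e),
                 wioa = wioa),
            class = "accuracy_block")
}

#' @export
print.accuracy_block <- function(x, ...) {
  cat(sprintf("rmse %.4f  r2 %.4f  mbe %+.4f  wioa %.4f\n",
              x$rmse, x$r2, x$mbe, x$wioa))
  invisible(x)
}

# OLS with conventional (homoskedastic) covariance on an explicit design.
# Returns coefficients, p-values, sigma2, vcov, residuals.
#' @noRd
ols_core <- function(Xd, y) {
  qrx <- qr(Xd)
  if (qrx$rank < ncol(Xd)) {
    bad <- colnames(Xd)[qrx$pivot[(qrx$rank + 1):ncol(Xd)]]
    stop(sprintf("rank-deficient design; collinear column(s): %s",
                 paste(bad, collapse = ", ")))
  }
  beta <- qr.coef(qrx, y)
  resid <- y - drop(Xd %*% beta)
  df <- length(y) - ncol(Xd)
  sigma2 <- sum(resid^2) / df
  XtXinv <- chol2inv(chol(crossprod(Xd)))
  dimnames(XtXinv) <- list(colnames(Xd), colnames(Xd))
  se <- sqrt(sigma2 * diag(XtXinv))
  pv <- 2 * pt(abs(beta / se), df, lower.tail = FALSE)
  list(beta = beta, se = se, pvalues = pv, sigma2 = sigma2,
       vcov = sigma2 * XtXinv, resid = resid, df = df)
}

#' @noRd
new_linear_fit <- function(model_id, beta, pvalues, constant, split,
                           train_pred, test_pred, sigma2, vcov_slopes,
                           entity_effects = NULL, time_effects = NULL,
                           extra = list()) {
  acc <- list(train = accuracy_block(split$y_train, train_pred),
              test = accuracy_block(split$y_test, test_pred))
  structure(c(list(model_id = model_id, beta = beta, pvalues = pvalues,
                   constant = constant, entity_effects = entity_effects,
                   time_effects = time_effects, residual_variance = sigma2,
                   vcov_slopes = vcov_slopes,
                   train_pred = train_pred, test_pred = test_pred,
                   accuracy = acc), extra),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("linear_fit [%s]: %d coefficients\n", x$model_id,
              length(x$beta)))
  cat("  train: "); print(x$accuracy$train)
  cat("  test:  "); print(x$accuracy$test)
  invisible(x)
}

#' Pooled ordinary least squares
#'
#' The baseline panel estimator: least squares of the scaled target on the
#' 23 scaled features plus an intercept (numerically near zero on scaled
#' data). Coefficients on scaled data are beta coefficients; p-values come
#' from the conventional homoskedastic covariance.
#'
#' @param split A `scaled_split`.
#' @return A `linear_fit`.
#' @export
fit_pooled_ols <- function(split) {
  stopifnot(inherits(split, "scaled_split"))
  p <- ncol(split$X_train)
  if (nrow(split$X_train) <= p + 1) stop("too few training rows")
  Xd <- cbind(`(intercept)` = 1, split$X_train)
  fit <- ols_core(Xd, split$y_train)
  beta <- fit$beta[-1]
  new_linear_fit("pooled_ols", beta, fit$pvalues[-1], fit$beta[1], split,
                 drop(Xd %*% fit$beta),
                 drop(cbind(1, split$X_test) %*% fit$beta),
                 fit$sigma2, fit$vcov[-1, -1, drop = FALSE])
}

# Build centred effect estimates from treatment-coded dummy coefficients.
#' @noRd
centre_effects <- function(coefs, levels, prefix) {
  eff <- setNames(rep(0, length(levels)), levels)
  got <- sub(prefix, "", names(coefs), fixed = TRUE)
  eff[got] <- coefs
  eff - mean(eff)
}

#' Fixed-effects estimators (FEE / FTE / FETE)
#'
#' Least-squares dummy-variable (LSDV) estimation: entity and/or year
#' indicators enter the design alongside the 23 features, so the slopes equal
#' the within-transformation estimator while the per-entity
#' \eqn{\hat\alpha_i} and per-year \eqn{\hat\gamma_t} remain reportable.
#' Effects are reported sum-to-zero (centred), with the grand constant
#' absorbing their means; predictions for test rows use the estimated effect
#' of the row's entity/year (0, i.e. the average, for a level unseen in
#' training).
#'
#' @param split A `scaled_split`.
#' @param entity Include entity effects?
#' @param time Include time effects?
#' @return A `linear_fit` with `entity_effects` and/or `time_effects` filled.
#' @export
fit_fixed_effects <- function(split, entity = TRUE, time = FALSE) {
  stopifnot(inherits(split, "scaled_split"))
  if (!entity && !time) stop("at least one of entity/time must be TRUE")
  model_id <- if (entity && time) "fete" else if (entity) "fee" else "fte"
  ent <- as.character(split$entity_train)
  yr <- as.character(split$year_train)
  if (entity && any(table(ent) < 2))
    stop("an entity has a single training row; cannot absorb its effect")
  if (time && any(table(yr) < 2))
    stop("a year has a single training row; cannot absorb its effect")
  p <- ncol(split$X_train)
  Xd <- cbind(`(intercept)` = 1, split$X_train)
  if (entity) {
    f <- factor(ent)
    D <- stats::model.matrix(~ f)[, -1, drop = FALSE]
    colnames(D) <- paste0("ent_", levels(f)[-1])
    Xd <- cbind(Xd, D)
  }
  if (time) {
    f <- factor(yr)
    D <- stats::model.matrix(~ f)[, -1, drop = FALSE]
    colnames(D) <- paste0("yr_", levels(f)[-1])
    Xd <- cbind(Xd, D)
  }
  fit <- ols_core(Xd, split$y_train)
  beta <- fit$beta[2:(p + 1)]
  pv <- fit$pvalues[2:(p + 1)]
  constant <- fit$beta[1]
  ent_eff <- yr_eff <- NULL
  if (entity) {
    ent_eff <- centre_effects(fit$beta[grep("^ent_", names(fit$beta))],
                              sort(unique(ent)), "ent_")
    constant <- constant + mean(fit$beta[grep("^ent_", names(fit$beta))] |>
                                  (\(z) c(0, z))())
  }
  if (time) {
    yr_eff <- centre_effects(fit$beta[grep("^yr_", names(fit$beta))],
                             sort(unique(yr)), "yr_")
    constant <- constant + mean(fit$beta[grep("^yr_", names(fit$beta))] |>
                                  (\(z) c(0, z))())
  }
  pred_for <- function(X, ents, yrs) {
    out <- drop(X %*% beta) + constant
    if (entity) {
      e <- ent_eff[as.character(ents)]
      e[is.na(e)] <- 0
      out <- out + e
    }
    if (time) {
      g <- yr_eff[as.character(yrs)]
      g[is.na(g)] <- 0
      out <- out + g
    }
    unname(out)
  }
  new_linear_fit(model_id, beta, pv, unname(constant), split,
                 pred_for(split$X_train, split$entity_train, split$year_train),
                 pred_for(split$X_test, split$entity_test, split$year_test),
                 fit$sigma2,
                 fit$vcov[2:(p + 1), 2:(p + 1), drop = FALSE],
                 entity_effects = ent_eff, time_effects = yr_eff)
}

#' Random-effects estimator (feasible GLS)
#'
#' One-way error-components model estimated by Swamy-Arora feasible GLS:
#' the idiosyncratic variance comes from the within (fixed-effects)
#' residuals, the entity-effect variance from the between regression, and the
#' model is estimated by OLS on quasi-demeaned data,
#' \eqn{z_{it} - \theta_i \bar z_i} with
#' \eqn{\theta_i = 1 - \sqrt{\sigma^2_\varepsilon /(\sigma^2_\varepsilon + T_i \sigma^2_\alpha)}}.
#' A negative estimated entity variance is clipped to zero with a warning
#' (the fit then collapses to pooled OLS).
#'
#' @param split A `scaled_split`.
#' @param variance_components Optional list `(sigma2_eps, sigma2_alpha)` to
#'   skip estimation (used for oracle comparisons against a hand-built GLS
#'   with known error covariance).
#' @return A `linear_fit` with a reported `constant` and the estimated
#'   variance components in `$variance_components`.
#' @export
fit_random_effects <- function(split, variance_components = NULL) {
  stopifnot(inherits(split, "scaled_split"))
  X <- split$X_train; y <- split$y_train
  ent <- as.character(split$entity_train)
  p <- ncol(X)
  if (is.null(variance_components)) {
    # within residual variance
    fe <- fit_fixed_effects(split, entity = TRUE, time = FALSE)
    n <- length(y); N <- length(unique(ent))
    ssr_w <- sum((y - fe$train_pred)^2)
    sigma2_eps <- ssr_w / (n - N - p)
    # between regression on entity means
    Xb <- aggregate_by_country(X, ent)
    yb <- drop(aggregate_by_country(matrix(y), ent))
    Ti <- as.vector(table(factor(ent, levels = rownames(Xb))))
    bfit <- ols_core(cbind(1, Xb), yb)
    s2_between <- sum(bfit$resid^2) / (N - p - 1)
    Tbar <- N / sum(1 / Ti)  # harmonic mean for unbalanced groups
    sigma2_alpha <- s2_between - sigma2_eps / Tbar
    if (sigma2_alpha < 0) {
      warning("negative entity variance component clipped to 0")
      sigma2_alpha <- 0
    }
  } else {
    sigma2_eps <- variance_components$sigma2_eps
    sigma2_alpha <- variance_components$sigma2_alpha
  }
  Ti_of <- table(ent)
  theta <- 1 - sqrt(sigma2_eps / (sigma2_eps + as.vector(Ti_of) * sigma2_alpha))
  names(theta) <- names(Ti_of)
  ybar <- tapply(y, ent, mean)
  Xbar <- aggregate_by_country(X, ent)
  yt <- y - theta[ent] * ybar[ent]
  Xt <- X - theta[ent] * Xbar[ent, , drop = FALSE]
  it <- 1 - theta[ent]
  fit <- ols_core(cbind(`(intercept)` = it, Xt), yt)
  beta <- fit$beta[-1]; constant <- fit$beta[1]
  tr_pred <- drop(split$X_train %*% beta) + constant
  te_pred <- drop(split$X_test %*% beta) + constant
  new_linear_fit("re", beta, fit$pvalues[-1], constant, split,
                 tr_pred, te_pred, sigma2_eps,
                 fit$vcov[-1, -1, drop = FALSE],
                 extra = list(variance_components =
                                list(sigma2_eps = sigma2_eps,
                                     sigma2_alpha = sigma2_alpha,
                                     theta = theta)))
}

#' Instrumental-variable two-stage least squares
#'
#' Structural equation: the 22 exogenous features plus the endogenous
#' welfare variable, with the instrument feature excluded from the structural
#' equation and used (with the exogenous features) in the first stage.
#' Following the reporting convention of the original analysis, the
#' coefficient on the instrumented variable is reported under the
#' instrument's label, so the coefficient vector still spans the 23 feature
#' names. Standard errors use the proper 2SLS covariance
#' \eqn{\hat\sigma^2 (\hat X'\hat X)^{-1}} with residuals from the observed
#' (not fitted) endogenous regressor.
#'
#' @param split A `scaled_split` whose panel carried a welfare variable.
#' @param endog Name under which the endogenous variable is known
#'   (bookkeeping only; the data come from `split$welfare_train`).
#' @param instrument Feature used as the instrument.
#' @return A `linear_fit` with `model_id = "iv2sls"` and first-stage
#'   statistics in `$first_stage`.
#' @export
fit_iv2sls <- function(split, endog = "welfare_25", instrument = "exposure") {
  stopifnot(inherits(split, "scaled_split"))
  if (is.null(split$welfare_train))
    stop("split carries no endogenous welfare variable")
  if (!instrument %in% colnames(split$X_train))
    stop(sprintf("instrument '%s' not among features", instrument))
  feats <- colnames(split$X_train)
  exog <- setdiff(feats, instrument)
  Xe_tr <- split$X_train[, exog, drop = FALSE]
  Xe_te <- split$X_test[, exog, drop = FALSE]
  w_tr <- split$welfare_train
  z_tr <- split$X_train[, instrument]

  # first stage: endogenous variable on exogenous features + instrument
  Z <- cbind(`(intercept)` = 1, Xe_tr, inst = z_tr)
  fs <- ols_core(Z, w_tr)
  w_hat <- w_tr - fs$resid
  fs_r2 <- 1 - sum(fs$resid^2) / sum((w_tr - mean(w_tr))^2)
  if (fs_r2 < 1e-6) stop("weak instrument: first-stage r2 below 1e-6")

  X2 <- cbind(`(intercept)` = 1, Xe_tr, endo = w_hat)
  fit2 <- ols_core(X2, split$y_train)
  beta_all <- fit2$beta
  # residuals with the *observed* endogenous regressor
  Xs <- cbind(1, Xe_tr, w_tr)
  resid <- split$y_train - drop(Xs %*% beta_all)
  df <- length(resid) - ncol(Xs)
  sigma2 <- sum(resid^2) / df
  XtXinv <- chol2inv(chol(crossprod(X2)))
  se <- sqrt(sigma2 * diag(XtXinv))
  pv <- 2 * pt(abs(beta_all / se), df, lower.tail = FALSE)
  vcov <- sigma2 * XtXinv
  dimnames(vcov) <- list(names(beta_all), names(beta_all))

  # report in 23-feature order, endogenous coefficient under instrument label
  beta <- setNames(numeric(length(feats)), feats)
  pvs <- beta
  beta[exog] <- beta_all[exog]; beta[instrument] <- beta_all[["endo"]]
  pvs[exog] <- pv[exog]; pvs[instrument] <- pv[["endo"]]

  tr_pred <- drop(cbind(1, Xe_tr, split$welfare_train) %*% beta_all)
  te_pred <- drop(cbind(1, Xe_te, split$welfare_test) %*% beta_all)
  new_linear_fit("iv2sls", beta, pvs, beta_all[[1]], split, tr_pred, te_pred,
                 sigma2, vcov[-1, -1, drop = FALSE],
                 extra = list(endog = endog, instrument = instrument,
                              first_stage = list(r2 = fs_r2,
                                                 coef = fs$beta)))
}

#' Specification tests
#'
#' * Hausman: \eqn{(b_{FE}-b_{RE})'(V_{FE}-V_{RE})^{+}(b_{FE}-b_{RE})} over
#'   the common slopes, with a pseudo-inverse when the variance difference is
#'   not positive definite; df = number of common slopes.
#' * Durbin / Wu-Hausman: residual-augmentation forms. With first-stage
#'   residuals \eqn{\hat v} added to the structural OLS,
#'   Durbin \eqn{= n (RSS_r - RSS_u)/RSS_r} (chi-squared, 1 df here) and
#'   Wu-Hausman is the corresponding F statistic.
#' * White: LM = n R-squared from regressing squared OLS residuals on the
#'   regressors, their squares and cross-products (collinear auxiliary
#'   columns dropped; df = achieved rank minus one).
#'
#' @param fee_fit `linear_fit` from [fit_fixed_effects()] (entity effects).
#' @param re_fit `linear_fit` from [fit_random_effects()] on the same design.
#' @param ols_fit `linear_fit` from [fit_pooled_ols()] (for the White test).
#' @param split The shared `scaled_split`.
#' @param iv List with `instrument` (and optionally `endog`) naming the
#'   IV2SLS pieces, or `NULL` to skip the exogeneity tests.
#' @return A `spec_tests` list: `hausman` (stat, df, p), `durbin` (stat, p),
#'   `wu_hausman` (stat, p), `white` (lm, df, p).
#' @export
specification_tests <- function(fee_fit, re_fit, ols_fit, split,
                                iv = list(instrument = "exposure")) {
  stopifnot(inherits(fee_fit, "linear_fit"), inherits(re_fit, "linear_fit"))
  common <- intersect(names(fee_fit$beta), names(re_fit$beta))
  if (length(common) == 0) stop("no common slopes between FE and RE fits")
  d <- fee_fit$beta[common] - re_fit$beta[common]
  Vd <- fee_fit$vcov_slopes[common, common] - re_fit$vcov_slopes[common, common]
  if (!all(dim(Vd) == length(common))) stop("non-conformable covariance matrices")
  ev <- eigen((Vd + t(Vd)) / 2, symmetric = TRUE)
  pos <- ev$values > max(ev$values) * 1e-10
  Vinv <- ev$vectors[, pos, drop = FALSE] %*%
    diag(1 / ev$values[pos], sum(pos)) %*% t(ev$vectors[, pos, drop = FALSE])
  h_stat <- max(0, drop(t(d) %*% Vinv %*% d))
  h_df <- length(common)
  hausman <- list(stat = h_stat, df = h_df,
                  p = pchisq(h_stat, h_df, lower.tail = FALSE))

  durbin <- wu <- NULL
  if (!is.null(iv)) {
    if (is.null(split$welfare_train))
      stop("exogeneity tests need the endogenous welfare variable")
    instrument <- iv$instrument %||% "exposure"
    exog <- setdiff(colnames(split$X_train), instrument)
    Xe <- split$X_train[, exog, drop = FALSE]
    w <- split$welfare_train
    z <- split$X_train[, instrument]
    v_hat <- ols_core(cbind(1, Xe, z), w)$resid
    y <- split$y_train
    rss_r <- sum(ols_core(cbind(1, Xe, w), y)$resid^2)
    rss_u <- sum(ols_core(cbind(1, Xe, w, v_hat), y)$resid^2)
    n <- length(y)
    d_stat <- n * (rss_r - rss_u) / rss_r
    durbin <- list(stat = d_stat, p = pchisq(d_stat, 1, lower.tail = FALSE))
    df2 <- n - (ncol(Xe) + 3)
    f_stat <- (rss_r - rss_u) / (rss_u / df2)
    wu <- list(stat = f_stat, p = pf(f_stat, 1, df2, lower.tail = FALSE))
  }

  white <- NULL
  if (!is.null(ols_fit)) {
    X <- split$X_train
    res2 <- (split$y_train - ols_fit$train_pred)^2
    sq <- X^2
    colnames(sq) <- paste0(colnames(X), "_sq")
    cross <- NULL
    p <- ncol(X)
    if (p > 1) {
      pairs <- utils::combn(p, 2)
      cross <- X[, pairs[1, ], drop = FALSE] * X[, pairs[2, ], drop = FALSE]
      colnames(cross) <- paste0(colnames(X)[pairs[1, ]], "_x_",
                                colnames(X)[pairs[2, ]])
    }
    A <- cbind(1, X, sq, cross)
    qa <- qr(A)
    if (qa$rank > length(res2) - 10) {
      # cross products exhaust the sample; squares-only (Koenker) form
      A <- cbind(1, X, sq)
      qa <- qr(A)
    }
    A <- A[, qa$pivot[seq_len(qa$rank)], drop = FALSE]
    fit <- ols_core(A, res2)
    r2 <- 1 - sum(fit$resid^2) / sum((res2 - mean(res2))^2)
    lm_stat <- length(res2) * r2
    df <- ncol(A) - 1
    white <- list(lm = lm_stat, df = df,
                  p = pchisq(lm_stat, df, lower.tail = FALSE))
  }
  structure(list(hausman = hausman, durbin = durbin, wu_hausman = wu,
                 white = white),
            class = "spec_tests")
}

#' @export
print.spec_tests <- function(x, ...) {
  cat(sprintf("Hausman chi2 = %.3f (df %d, p %.4g)\n",
              x$hausman$stat, x$hausman$df, x$hausman$p))
  if (!is.null(x$durbin))
    cat(sprintf("Durbin = %.4f (p %.4g); Wu-Hausman = %.4f (p %.4g)\n",
                x$durbin$stat, x$durbin$p, x$wu_hausman$stat, x$wu_hausman$p))
  if (!is.null(x$white))
    cat(sprintf("White LM = %.3f (df %d, p %.4g)\n",
                x$white$lm, x$white$df, x$white$p))
  invisible(x)
}

#' Export linear fits as a coefficient table with significance stars
#'
#' One row per feature, one coefficient column per fit, with stars at the
#' 0.001/0.01/0.05/0.1 thresholds (`***`, `**`, `*`, `+`).
#'
#' @param fits List of `linear_fit` objects.
#' @param path Optional CSV path.
#' @return The table (invisibly if written to file).
#' @export
export_linear_table <- function(fits, path = NULL) {
  stars <- function(p) ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", ifelse(p < 0.1, "+", ""))))
  out <- data.frame(variable = names(fits[[1]]$beta))
  for (f in fits) {
    out[[f$model_id]] <- unname(f$beta)
    out[[paste0(f$model_id, "_sig")]] <- stars(unname(f$pvalues))
  }
  if (!is.null(path)) {
    write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
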