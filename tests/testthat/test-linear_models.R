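test_that("accuracy block matches its defining formulas", {
  obs <- c(1, 2, 3)
  expect_warning(acc0 <- accuracy_block(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_true(is.na(acc0$r2))

  perfect <- accuracy_block(obs, obs)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$mbe, 0)
  expect_equal(perfect$wioa, 1)

  shifted <- accuracy_block(obs, obs + 0.5)
  expect_equal(shifted$mbe, 0.5)
  expect_equal(shifted$rmse, 0.5)

  # three-point hand computation of Willmott's index:
  # obs (1,2,3), pred (1.5, 1.5, 3.5): sum(p-o)^2 = 0.75;
  # obar = 2; sum(|p-obar| + |o-obar|)^2 = (0.5+1)^2 + (0.5+0)^2 + (1.5+1)^2
  # = 2.25 + 0.25 + 6.25 = 8.75; wioa = 1 - 0.75/8.75
  hand <- accuracy_block(obs, c(1.5, 1.5, 3.5))
  expect_equal(hand$wioa, 1 - 0.75 / 8.75)
  expect_error(accuracy_block(1:3, 1:2), "lengths differ")
})

test_that("pooled OLS equals the normal-equations oracle and is exact on noiseless data", {
  set.seed(11)
  Xtr <- matrix(rnorm(36), 12, 3, dimnames = list(NULL, c("a", "b", "c")))
  Xte <- matrix(rnorm(9), 3, 3, dimnames = list(NULL, c("a", "b", "c")))
  beta <- c(2, -1, 0.5)
  ytr <- drop(Xtr %*% beta); yte <- drop(Xte %*% beta)
  sp <- manual_split(Xtr, ytr, Xte, yte)
  fit <- fit_pooled_ols(sp)
  # exact recovery, r2 = 1
  expect_equal(unname(fit$beta), beta, tolerance = 1e-8)
  expect_equal(fit$accuracy$train$r2, 1, tolerance = 1e-12)
  # normal-equations oracle (X'X)^-1 X'y on a noisy toy
  ytr2 <- ytr + rnorm(12, 0, 0.5)
  sp2 <- manual_split(Xtr, ytr2, Xte, yte)
  fit2 <- fit_pooled_ols(sp2)
  X1 <- cbind(1, Xtr)
  oracle <- unname(drop(solve(t(X1) %*% X1) %*% t(X1) %*% ytr2))
  expect_equal(unname(fit2$beta), oracle[-1], tolerance = 1e-10)
  expect_equal(unname(fit2$constant), oracle[1], tolerance = 1e-10)
  # rank-deficient design names the collinear column
  Xbad <- cbind(Xtr, d = Xtr[, "a"])
  expect_error(fit_pooled_ols(manual_split(Xbad, ytr, cbind(Xte, d = Xte[, "a"]), yte)),
               "collinear")
})

test_that("standardized coefficients are invariant to raw feature rescaling", {
  panel <- generate_panel(generator_config())
  f1 <- fit_pooled_ols(scaled_split(panel))
  panel2 <- panel
  panel2$X[, "gini"] <- panel2$X[, "gini"] * 1000
  f2 <- fit_pooled_ols(scaled_split(panel2))
  expect_equal(f1$beta, f2$beta, tolerance = 1e-8)
  expect_equal(f1$pvalues, f2$pvalues, tolerance = 1e-8)
})

test_that("fixed-effects estimators recover entity structure and report full effect vectors", {
  cfg <- small_cfg(entity_sd = 1, noise = 0.05)
  panel <- generate_panel(cfg)
  sp <- scaled_split(panel, seed = 1)
  fee <- fit_fixed_effects(sp, entity = TRUE)
  truth <- panel$truth_effects$alpha
  truth_c <- truth - mean(truth)
  expect_gt(cor(fee$entity_effects[names(truth)], truth_c), 0.99)

  # FETE on the default panel returns 27 entity and 11 year effects
  big <- default_panel_split()$split
  fete <- fit_fixed_effects(big, entity = TRUE, time = TRUE)
  expect_length(fete$entity_effects, 27)
  expect_length(fete$time_effects, 11)
  expect_equal(fete$model_id, "fete")
  # effects reported sum-to-zero
  expect_equal(sum(fete$entity_effects), 0, tolerance = 1e-8)
  expect_equal(sum(fete$time_effects), 0, tolerance = 1e-8)
  expect_error(fit_fixed_effects(big, entity = FALSE, time = FALSE),
               "at least one")
})

test_that("with zero entity effects FEE slopes collapse to pooled OLS", {
  cfg <- small_cfg(entity_sd = 0, noise = 0.3, seed = 3)
  sp <- scaled_split(generate_panel(cfg), seed = 3)
  fee <- fit_fixed_effects(sp, entity = TRUE)
  ols <- fit_pooled_ols(sp)
  se <- sqrt(diag(ols$vcov_slopes))
  expect_lt(max(abs(fee$beta - ols$beta) / se), 2)
})

test_that("random effects equals a hand-built GLS with the same error covariance", {
  cfg <- small_cfg(n_entities = 3, years = 2001:2010, entity_sd = 0.5,
                   noise = 0.4, seed = 9)
  sp <- scaled_split(generate_panel(cfg), test_fraction = 0.1, seed = 9)
  vc <- list(sigma2_eps = 0.16, sigma2_alpha = 0.25)  # known components
  re <- fit_random_effects(sp, variance_components = vc)
  # hand GLS: Omega = sigma2_eps I + sigma2_alpha (block ones), train rows
  ent <- sp$entity_train
  n <- length(sp$y_train)
  Omega <- vc$sigma2_eps * diag(n) +
    vc$sigma2_alpha * outer(ent, ent, "==")
  Oi <- solve(Omega)
  X1 <- cbind(1, sp$X_train)
  bg <- unname(drop(solve(t(X1) %*% Oi %*% X1) %*% t(X1) %*% Oi %*%
                      sp$y_train))
  expect_equal(unname(re$constant), bg[1], tolerance = 1e-8)
  expect_equal(unname(re$beta), unname(bg[-1]), tolerance = 1e-8)
})

test_that("with no entity variance random effects collapses to pooled OLS", {
  cfg <- small_cfg(entity_sd = 0, noise = 0.3, seed = 5)
  sp <- scaled_split(generate_panel(cfg), seed = 5)
  re <- suppressWarnings(
    fit_random_effects(sp, variance_components = list(sigma2_eps = 1,
                                                      sigma2_alpha = 0)))
  ols <- fit_pooled_ols(sp)
  expect_equal(re$beta, ols$beta, tolerance = 1e-10)
})

test_that("IV2SLS matches the two-stage-by-hand oracle and the perfect-instrument limit", {
  ps <- default_panel_split()
  sp <- ps$split
  iv <- fit_iv2sls(sp)
  # hand oracle: first stage, substitute fitted values, OLS
  exog <- setdiff(colnames(sp$X_train), "exposure")
  fs <- lm(sp$welfare_train ~ sp$X_train[, exog] + sp$X_train[, "exposure"])
  w_hat <- fitted(fs)
  second <- lm(sp$y_train ~ sp$X_train[, exog] + w_hat)
  cf <- coef(second)
  expect_equal(unname(iv$beta[exog]),
               unname(cf[2:(length(exog) + 1)]), tolerance = 1e-8)
  expect_equal(unname(iv$beta["exposure"]), unname(cf[length(cf)]),
               tolerance = 1e-8)
  # the instrumented coefficient is reported under the instrument's label
  expect_named(iv$beta, colnames(sp$X_train), ignore.order = TRUE)

  # perfect-instrument limit: welfare identical to the instrument column
  panel2 <- ps$panel
  panel2$welfare <- panel2$X[, "exposure"]
  sp2 <- scaled_split(panel2)
  iv2 <- fit_iv2sls(sp2)
  ols2 <- fit_pooled_ols(sp2)
  expect_equal(iv2$beta, ols2$beta, tolerance = 1e-8)
})

test_that("IV2SLS train r2 never exceeds pooled OLS on the same sample", {
  sp <- default_panel_split()$split
  iv <- fit_iv2sls(sp)
  # pooled OLS on the same structural design (22 exog + observed welfare)
  exog <- setdiff(colnames(sp$X_train), "exposure")
  ols_fit <- lm(sp$y_train ~ sp$X_train[, exog] + sp$welfare_train)
  ols_r2 <- summary(ols_fit)$r.squared
  expect_lte(iv$accuracy$train$r2, ols_r2 + 1e-10)
})

test_that("specification tests return valid statistics on the default panel", {
  sp <- default_panel_split()$split
  fee <- fit_fixed_effects(sp, entity = TRUE)
  re <- suppressWarnings(fit_random_effects(sp))
  ols <- fit_pooled_ols(sp)
  st <- specification_tests(fee, re, ols, sp)
  expect_gte(st$hausman$stat, 0)
  expect_equal(st$hausman$df, 23)
  expect_true(st$hausman$p >= 0 && st$hausman$p <= 1)
  expect_gt(st$durbin$stat, 0)
  expect_gt(st$wu_hausman$stat, 0)
  expect_true(st$white$p >= 0 && st$white$p <= 1)
  # endogenous welfare in the default generator is detected
  expect_lt(st$durbin$p, 0.01)
  expect_lt(st$wu_hausman$p, 0.01)
})

test_that("coefficient export carries significance stars", {
  sp <- default_panel_split()$split
  tab <- export_linear_table(list(fit_pooled_ols(sp)))
  expect_equal(nrow(tab), 23)
  expect_true(all(c("pooled_ols", "pooled_ols_sig") %in% colnames(tab)))
  expect_true(all(tab$pooled_ols_sig %in% c("", "+", "*", "**", "***")))
})
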