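test_that("column weighting is elementwise and tags prior/posterior", {
  set.seed(41)
  X <- matrix(rnorm(60), 12, 5, dimnames = list(NULL, letters[1:5]))
  w <- c(0.5, 0.2, 0.1, 0.15, 0.05)
  wa <- weight_columns(X, w)
  # loop oracle
  for (i in seq_len(12)) for (j in seq_len(5))
    expect_equal(unclass(wa)[i, j], X[i, j] * w[j])
  expect_equal(attr(wa, "weighting_tag"), "posterior")
  # uniform weights give the prior tag and a global rescale
  prior <- weight_columns(X)
  expect_equal(attr(prior, "weighting_tag"), "prior")
  expect_equal(unclass(prior), X / 5, ignore_attr = TRUE)
  # one-hot weights zero out all but one column
  oh <- weight_columns(X, c(1, 0, 0, 0, 0))
  expect_equal(unname(colSums(abs(unclass(oh)))[-1]), rep(0, 4))
  expect_error(weight_columns(X, c(-1, 1, 1, 1, 1)), "negative")
  expect_error(weight_columns(X, c(1, 2)), "one weight per column")
})

test_that("affinity propagation separates three blobs and is deterministic", {
  set.seed(42)
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10))
  X <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(40, sd = 0.5), 20, 2), 2, centers[k, ], "+")))
  # append duplicated rows
  X <- rbind(X, X[1, ], X[1, ])
  cl <- cluster_affinity(X)
  expect_equal(cl$n_clusters, 3)
  truth <- c(rep(1:3, each = 20), 1, 1)
  expect_equal(length(unique(paste(cl$labels, truth))), 3)
  # exemplars live inside their own cluster
  expect_equal(cl$labels[cl$exemplars], seq_len(cl$n_clusters))
  # duplicated rows share a label
  expect_equal(cl$labels[61], cl$labels[1])
  expect_equal(cl$labels[62], cl$labels[1])
  # deterministic given parameters
  cl2 <- cluster_affinity(X)
  expect_identical(cl$labels, cl2$labels)
  expect_identical(cl$exemplars, cl2$exemplars)
  expect_error(cluster_affinity(X[1, , drop = FALSE]), "at least 2")
  expect_error(cluster_affinity(X, damping = 0.4), "damping")
})

test_that("PCA embedding recovers a rank-1 generating direction", {
  set.seed(43)
  t <- rnorm(80)
  load <- runif(23)
  X <- outer(t, load) + matrix(rnorm(80 * 23, sd = 1e-6), 80, 23)
  emb <- embed_array(X, "pca", k = 1)
  expect_equal(abs(cor(emb$coordinates[, 1], t)), 1, tolerance = 1e-6)
  expect_gt(emb$metadata$explained_variance[1], 0.999)
  expect_error(embed_array(X, "umap", k = 1), "arg")
  expect_error(embed_array(X, "pca", k = 23), "smaller")
})

test_that("isomap and LLE order points along a noiseless curve", {
  t <- seq(0, 1, length.out = 100)
  # smooth open 1-D curve embedded in 23 dimensions (gentle frequencies,
  # so the curve never folds back on itself)
  X <- sapply(seq_len(23), function(j)
    sin((0.5 + 0.1 * (j %% 5)) * t + j / 3))
  for (m in c("isomap", "lle")) {
    emb <- embed_array(X, m, k = 1, n_neighbors = 10)
    rho <- cor(emb$coordinates[, 1], t, method = "spearman")
    expect_gt(abs(rho), 0.95)
  }
})

test_that("MDS yields requested dimensions with non-increasing stress", {
  set.seed(44)
  X <- matrix(rnorm(60 * 6), 60, 6)
  e3 <- embed_array(X, "mds", k = 3)
  expect_equal(dim(e3$coordinates), c(60, 3))
  e1 <- embed_array(X, "mds", k = 1)
  expect_lte(e3$metadata$stress, e1$metadata$stress)
})

test_that("t-SNE and factor embeddings return finite coordinates of the right shape", {
  set.seed(45)
  X <- matrix(rnorm(90 * 8), 90, 8)
  ts <- embed_array(X, "tsne", k = 2, perplexity = 15)
  expect_equal(dim(ts$coordinates), c(90, 2))
  expect_true(all(is.finite(ts$coordinates)))
  fa <- embed_array(X, "factor", k = 1)
  expect_equal(dim(fa$coordinates), c(90, 1))
})

test_that("predictive manifolds are standardized, sign-aligned z-scores", {
  pipe <- default_pipeline()
  y <- pipe$split$full_scaled_y
  for (m in pipe$manifolds) {
    expect_equal(mean(m$z), 0, tolerance = 1e-9)
    expect_equal(sqrt(mean((m$z - mean(m$z))^2)), 1, tolerance = 1e-9)
    expect_gte(cor(m$z, y), 0)
  }
  # a dominant-variance direction equal to the target is recovered
  set.seed(46)
  yy <- rnorm(120)
  X <- outer(yy, runif(10, 0.5, 1)) + matrix(rnorm(1200, sd = 0.05), 120, 10)
  pm <- predictive_manifold(X, "pca", yy)
  expect_gt(pm$accuracy$r2, 0.9)
  expect_error(predictive_manifold(matrix(5, 30, 4), "pca", rnorm(30)),
               "zero-variance")
})

test_that("the MDS ecliptic fits the plane of the first two coordinates", {
  set.seed(47)
  X <- matrix(rnorm(80 * 6), 80, 6)
  co <- embed_array(X, "mds", k = 3, seed = 1)$coordinates
  y0 <- 2 * co[, 1] - co[, 2]
  y <- (y0 - mean(y0)) / sqrt(mean((y0 - mean(y0))^2))
  ec <- mds_ecliptic(X, y, seed = 1)
  expect_gt(ec$accuracy$r2, 0.999)
  expect_equal(mean(ec$z), 0, tolerance = 1e-9)
  # nesting on the shared default array: two MDS dimensions explain at
  # least as much as the single-dimension MDS manifold
  pipe <- default_pipeline()
  expect_gte(pipe$ecliptic$accuracy$r2 + 1e-8,
             pipe$manifolds$mds$accuracy$r2)
})

test_that("the unsupervised-OLS blend dominates its inputs and matches the oracle", {
  set.seed(48)
  n <- 100
  y <- rnorm(n)
  z1 <- standardize <- function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  mk <- function(v, tag) structure(list(method = tag, z = z1(v),
                                        accuracy = accuracy_block(y, z1(v))),
                                   class = "manifold_prediction")
  ms <- list(mk(y + rnorm(n, 0, 0.8), "a"), mk(y + rnorm(n, 0, 1.5), "b"),
             mk(rnorm(n), "c"))
  blend <- unsupervised_ols_blend(ms, y)
  for (m in ms) expect_gte(blend$accuracy$r2 + 1e-10, m$accuracy$r2)
  # coefficients equal the normal-equations oracle
  Z <- cbind(1, sapply(ms, `[[`, "z"))
  oracle <- drop(solve(t(Z) %*% Z) %*% t(Z) %*% y)
  expect_equal(unname(blend$coefficients), oracle, tolerance = 1e-10)
  # an input equal to the (standardized) target gives a perfect blend
  blend2 <- unsupervised_ols_blend(list(mk(z1(y), "t"), ms[[3]]), z1(y))
  expect_equal(blend2$accuracy$r2, 1, tolerance = 1e-9)
  expect_error(unsupervised_ols_blend(ms[1], y), "at least 2")
  # collinear stacks are pruned with a warning
  expect_warning(unsupervised_ols_blend(list(ms[[1]], ms[[1]], ms[[2]]), y),
                 "collinear")
})

test_that("posterior weighting does not reduce mean manifold accuracy", {
  pipe <- default_pipeline()
  methods <- names(pipe$manifolds)
  prior <- weight_columns(pipe$split$full_scaled_X)
  prior_r2 <- sapply(methods, function(m)
    predictive_manifold(prior, m, pipe$split$full_scaled_y,
                        seed = 1)$accuracy$r2)
  post_r2 <- sapply(pipe$manifolds, function(m) m$accuracy$r2)
  expect_gte(mean(post_r2), mean(prior_r2))
})

test_that("country-aggregate clustering yields a plausible cluster count", {
  pipe <- default_pipeline()
  for (cl in pipe$clusters) {
    expect_gte(cl$n_clusters, 2)
    expect_lte(cl$n_clusters, 27)
    expect_length(cl$labels, 27)
  }
})
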