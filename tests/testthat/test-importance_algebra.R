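test_that("emulated importances follow the |beta|(1-p)^gamma transform", {
  # analytic: beta (1,2), p (0.5,0.5), gamma 2 -> (1/3, 2/3)
  f <- emulate_importances(c(1, 2), c(0.5, 0.5), gamma = 2)
  expect_equal(as.numeric(f), c(1 / 3, 2 / 3))
  # a single nonzero beta gives a one-hot vector
  f2 <- emulate_importances(c(0, 0, -3), c(0.2, 0.9, 0.4))
  expect_equal(as.numeric(f2), c(0, 0, 1))
  # every p = 1 annihilates the numerator: an error, not a uniform vector
  expect_error(emulate_importances(c(1, 2), c(1, 1)), "all-zero numerator")
  expect_error(emulate_importances(c(1, 2), c(0.5, 1.2)), "pvalues")
})

test_that("emulated importances are normalized and monotone", {
  set.seed(31)
  for (i in 1:20) {
    beta <- rnorm(23)
    p <- runif(23)
    f <- emulate_importances(beta, p)
    expect_prob_vector(as.numeric(f), 23)
    # raising |beta_v| never decreases f_v
    v <- sample(23, 1)
    beta2 <- beta
    beta2[v] <- beta2[v] * 2 + sign(beta2[v]) * 0.5
    f2 <- emulate_importances(beta2, p)
    expect_gte(f2[v], f[v])
    # raising p_v never increases f_v
    p3 <- p
    p3[v] <- min(1, p3[v] + 0.3)
    f3 <- emulate_importances(beta, p3)
    expect_lte(f3[v] - f[v], 1e-12)
  }
})

test_that("Gini coefficient matches its closed forms and the pairwise oracle", {
  expect_equal(as.numeric(gini_coefficient(rep(0.2, 10))), 0)
  one_hot <- c(rep(0, 22), 1)
  expect_equal(as.numeric(gini_coefficient(one_hot)), 22 / 23)
  expect_error(gini_coefficient(c(-1, 2)), "negative")
  expect_error(gini_coefficient(c(0, 0)), "positive sum")
  # brute-force pairwise-difference oracle sum|xi-xj| / (2 n^2 mu)
  set.seed(13)
  for (i in 1:10) {
    v <- runif(sample(5:40, 1))
    pair <- sum(abs(outer(v, v, "-"))) / (2 * length(v)^2 * mean(v))
    expect_equal(as.numeric(gini_coefficient(v)), pair, tolerance = 1e-12)
  }
  # Lorenz points are the cumulative ascending shares
  g <- gini_coefficient(c(3, 1, 2))
  lor <- attr(g, "lorenz")
  expect_equal(lor$weight_share, cumsum(sort(c(3, 1, 2))) / 6)
})

test_that("Simpson's index and its reciprocal behave on uniform and one-hot vectors", {
  u <- simpson_index(rep(1, 23))
  expect_equal(u$simpson, 1 / 23)
  expect_equal(u$inv_simpson, 23)
  oh <- simpson_index(c(rep(0, 9), 5))
  expect_equal(oh$simpson, 1)
  expect_equal(oh$inv_simpson, 1)
  expect_error(simpson_index(rep(0, 4)), "zero")
})

test_that("diversity statistics recompute the published tables from the shipped fixtures", {
  # printed diversity values for the six tree ensembles and six linear
  # models; agreement is bounded by the 6-decimal rounding of the printed
  # importance tables they are recomputed from (propagated bound ~5e-5)
  ml <- pm25_reference_importances("ml_importances")
  lin <- pm25_reference_importances("emulated_importances")
  printed_ml <- rbind(
    gini = c(0.733565, 0.687512, 0.825314, 0.879177, 0.745226, 0.313739),
    simpson = c(0.219090, 0.166459, 0.281478, 0.532226, 0.213564, 0.063896),
    inv_simpson = c(4.564335, 6.007497, 3.552676, 1.878900, 4.682437,
                    15.650432))
  printed_lin <- rbind(
    gini = c(0.640728, 0.729023, 0.608118, 0.636847, 0.626618, 0.698973),
    simpson = c(0.113195, 0.167060, 0.100787, 0.110444, 0.112763, 0.201177),
    inv_simpson = c(8.834318, 5.985860, 9.921939, 9.054360, 8.868171,
                    4.970742))
  for (j in seq_len(6)) {
    s_ml <- simpson_index(unclass(ml)[, j])
    expect_equal(s_ml$gini, unname(printed_ml["gini", j]), tolerance = 5e-5)
    expect_equal(s_ml$simpson, unname(printed_ml["simpson", j]), tolerance = 5e-5)
    expect_equal(s_ml$inv_simpson, unname(printed_ml["inv_simpson", j]),
                 tolerance = 5e-5)
    s_lin <- simpson_index(unclass(lin)[, j])
    expect_equal(s_lin$gini, unname(printed_lin["gini", j]), tolerance = 5e-5)
    expect_equal(s_lin$simpson, unname(printed_lin["simpson", j]), tolerance = 5e-5)
    expect_equal(s_lin$inv_simpson, unname(printed_lin["inv_simpson", j]),
                 tolerance = 5e-5)
  }
})

test_that("F = (L | M) concatenation checks labels and keeps columns stochastic", {
  L <- pm25_reference_importances("emulated_importances")
  M <- pm25_reference_importances("ml_importances")
  F_mat <- concat_importance_matrix(L, M)
  expect_equal(dim(F_mat), c(23, 12))
  expect_equal(unname(colSums(unclass(F_mat))), rep(1, 12), tolerance = 1e-9)
  expect_equal(attr(F_mat, "provenance"),
               c(rep("emulated", 6), rep("actual", 6)))
  # linear columns first
  expect_equal(colnames(F_mat)[1:6], colnames(L))
  # permuted row labels are refused with the offending rows named
  M2 <- unclass(M)[c(2, 1, 3:23), ]
  expect_error(concat_importance_matrix(L, importance_matrix(M2)),
               "mismatch")
})

test_that("V = F W conserves total importance and matches the loop oracle", {
  F_mat <- concat_importance_matrix(
    pm25_reference_importances("emulated_importances"),
    pm25_reference_importances("ml_importances"))
  # one-hot W selects the corresponding column
  W1 <- c(1, rep(0, 11))
  V1 <- aggregate_importances(F_mat, W1)
  expect_equal(as.numeric(V1), unname(unclass(F_mat)[, 1]))
  # stochastic W: sum V = 1 exactly (algebraic conservation)
  set.seed(4)
  W <- runif(12); W <- W / sum(W)
  V <- aggregate_importances(F_mat, W)
  expect_equal(sum(V), 1, tolerance = 1e-12)
  # explicit double-loop oracle
  oracle <- sapply(seq_len(23), function(v)
    sum(sapply(seq_len(12), function(m) unclass(F_mat)[v, m] * W[m])))
  expect_equal(as.numeric(V), oracle, tolerance = 1e-14)
  expect_error(aggregate_importances(F_mat, W[1:5]), "non-conformable")
  expect_error(aggregate_importances(F_mat, W * 2), "sum to 1")
})

test_that("diversity table export reports the three indexes per model", {
  tab <- export_diversity_table(pm25_reference_importances("ml_importances"))
  expect_equal(tab$index, c("gini", "simpson", "inv_simpson"))
  expect_equal(ncol(tab), 7)
})
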