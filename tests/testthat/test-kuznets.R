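test_that("composite indexes use the documented group slices and orientation", {
  pipe <- default_pipeline()
  expect_length(pipe$econ_index$variables, 11)
  expect_length(pipe$health_index$variables, 12)
  expect_length(pipe$econ_index$values, 27)
  expect_true(all(is.finite(pipe$econ_index$values)))
  # orientation anchors: positive correlation with the anchor column means
  # country-mean anchors by construction
  sp <- pipe$split
  gdp <- drop(aggregate_by_country(
    matrix(unclass(pipe$posterior)[, "real_gdp_pc"]), sp$entity))
  expect_gt(cor(pipe$econ_index$values, gdp), 0)
  expo <- drop(aggregate_by_country(
    matrix(unclass(pipe$posterior)[, "exposure"]), sp$entity))
  expect_gt(cor(pipe$health_index$values, expo), 0)
  expect_error(composite_index(matrix(1, 10, 23,
                                      dimnames = list(NULL, names(pm25_group_map()))),
                               "economic", rep(letters[1:2], 5)),
               "constant")
})

test_that("the economic index recovers the latent economic factor", {
  pipe <- default_pipeline()
  econ_feats <- names(pm25_group_map())[pm25_group_map() == "economic"]
  proxy <- rowMeans(aggregate_by_country(
    pipe$split$full_scaled_X[, econ_feats], pipe$split$entity))
  expect_gt(abs(cor(pipe$econ_index$values, proxy)), 0.95)
})

test_that("the composite index is invariant to translating a raw feature", {
  ps <- default_panel_split()
  panel2 <- ps$panel
  panel2$X[, "spending"] <- panel2$X[, "spending"] + 100
  sp2 <- scaled_split(panel2)
  i1 <- composite_index(weight_columns(ps$split$full_scaled_X),
                        "economic", ps$panel$entity)
  i2 <- composite_index(weight_columns(sp2$full_scaled_X),
                        "economic", panel2$entity)
  expect_equal(i1$values, i2$values, tolerance = 1e-10)
})

test_that("polynomial Kuznets fits are exact on a parabola and match the Vandermonde oracle", {
  x <- seq(-2, 2, length.out = 27)
  y <- 1 + 2 * x - 3 * x^2
  kc <- kuznets_curves(x, y)
  expect_lt(kc$residual_ss[["degree_2"]], 1e-9)
  # the averaged degree-2/3/4 curve reproduces the parabola on the grid
  expect_equal(kc$average_curve, 1 + 2 * kc$grid - 3 * kc$grid^2,
               tolerance = 1e-6)
  # degree-d coefficient vectors have d+1 entries and match the
  # Vandermonde normal-equations oracle on noisy data
  set.seed(51)
  y2 <- y + rnorm(27, 0, 0.3)
  kc2 <- kuznets_curves(x, y2)
  for (d in 1:4) {
    expect_length(kc2$fits[[d]], d + 1)
    V <- outer(x, 0:d, "^")
    oracle <- drop(solve(t(V) %*% V) %*% t(V) %*% y2)
    expect_equal(kc2$fits[[d]], oracle, tolerance = 1e-8)
  }
  expect_error(kuznets_curves(x[1:4], y[1:4]), "at least 5")
})

test_that("the published country index/mortality pairs are accepted as direct input", {
  tab <- pm25_reference_table("kuznets_economic")
  expect_equal(nrow(tab), 27)
  kc <- kuznets_curves(tab$economic_index, tab$pm25_mortality)
  expect_length(kc$fits$degree_2, 3)
  expect_true(all(is.finite(kc$average_curve)))
  # higher-degree fits never increase the residual sum of squares
  expect_true(all(diff(kc$residual_ss) <= 1e-8))
  # on the display convention (mortality axis inverted so good outcomes
  # point up) the quadratic term opens downward: the inverted U
  kc_inv <- kuznets_curves(tab$economic_index, -tab$pm25_mortality)
  expect_lt(kc_inv$fits$degree_2[3], 0)
})

test_that("cluster ellipses equal the covariance eigenstructure", {
  set.seed(52)
  pts <- matrix(rnorm(1000), 500, 2)
  e <- cluster_ellipse(pts, rep("a", 500))
  # isotropic cloud: near-circular ellipse
  expect_gt(e$axis_minor / e$axis_major, 0.8)
  expect_lte(e$axis_minor / e$axis_major, 1)
  # axes equal sqrt eigenvalues of the cluster covariance
  ev <- eigen(cov(pts))$values
  expect_equal(c(e$axis_major, e$axis_minor), sqrt(ev))
  # anisotropic cluster tilts along its principal direction
  pts2 <- cbind(rnorm(200), 0) %*% rbind(c(cos(0.5), sin(0.5)), c(0, 1)) +
    matrix(rnorm(400, sd = 0.1), 200, 2)
  e2 <- cluster_ellipse(pts2, rep("b", 200))
  # tilt is an axis orientation, defined modulo pi
  expect_equal(e2$tilt %% pi, 0.5, tolerance = 0.1)
  # degenerate two-point cluster gets a flagged fallback
  both <- cluster_ellipse(rbind(pts, c(9, 9), c(9.1, 9)),
                          c(rep("a", 500), "tiny", "tiny"))
  expect_true(both$degenerate[both$label == "tiny"])
  expect_false(both$degenerate[both$label == "a"])
  expect_error(cluster_ellipse(pts[0, ], character(0)), "empty")
})

test_that("sundew plot data reports per-observation distances", {
  obs <- c(1, 2, 3)
  d <- sundew_plot_data(obs, obs, obs)
  expect_equal(d$dist_a, c(0, 0, 0))
  # three-point hand computation
  d2 <- sundew_plot_data(obs, c(1.5, 1.5, 2.5), c(0.5, 2.5, 3.5))
  expect_equal(d2$dist_a, c(0.5, 0.5, 0.5))
  expect_equal(d2$dist_b, c(0.5, 0.5, 0.5))
  expect_true(all(d2$dist_a >= 0 & d2$dist_b >= 0))
  expect_error(sundew_plot_data(obs, obs, obs[1:2]), "length")
})

test_that("Kuznets table export aligns countries by name", {
  pipe <- default_pipeline()
  tab <- export_kuznets_table(pipe$econ_index, pipe$country_mortality)
  expect_equal(nrow(tab), 27)
  expect_equal(tab$country, names(pipe$econ_index$values))
})
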