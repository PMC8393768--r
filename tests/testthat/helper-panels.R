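# Shared builders for the test suite. Heavyweight objects (the default-panel
# pipeline run) are memoized so several files can share one computation.

.cache <- new.env(parent = emptyenv())

# A small three-feature generator config for quick simulations.
small_cfg <- function(seed = 1, n_entities = 15, years = 2001:2008,
                      beta = c(0.5, -0.3, 0.2), entity_sd = 0.4,
                      noise = 0.5, loading = 0.5, ar = 0.7,
                      year_trend = rep(0, length(years))) {
  generator_config(
    n_entities = n_entities, years = years,
    feature_names = c("exposure", "x2", "x3"),
    group_map = c(exposure = "health", x2 = "economic", x3 = "economic"),
    beta_true = beta, entity_effect_sd = entity_sd,
    year_trend = year_trend, noise_sd = noise,
    latent_loading = loading, factor_ar = ar, seed = seed)
}

# Build a scaled_split directly from raw matrices (for oracle tests that
# need full control of the design).
manual_split <- function(X_train, y_train, X_test, y_test,
                         entity_train = NULL, year_train = NULL,
                         entity_test = NULL, year_test = NULL,
                         welfare_train = NULL, welfare_test = NULL) {
  structure(list(
    train_idx = seq_len(nrow(X_train)),
    test_idx = nrow(X_train) + seq_len(nrow(X_test)),
    scaler = list(center = colMeans(X_train),
                  scale = rep(1, ncol(X_train)), y_center = 0, y_scale = 1),
    X_train = X_train, X_test = X_test,
    y_train = y_train, y_test = y_test,
    welfare_train = welfare_train, welfare_test = welfare_test,
    full_scaled_X = rbind(X_train, X_test),
    full_scaled_y = c(y_train, y_test),
    entity = c(entity_train, entity_test),
    year = c(year_train, year_test),
    entity_train = entity_train, entity_test = entity_test,
    year_train = year_train, year_test = year_test),
    class = "scaled_split")
}

# Default panel with welfare, no missingness, plus its scaled split.
default_panel_split <- function() {
  if (is.null(.cache$dps)) {
    panel <- generate_endogenous_welfare(generate_panel(generator_config()))
    .cache$dps <- list(panel = panel, split = scaled_split(panel))
  }
  .cache$dps
}

# One shared pipeline run on the default conditions (moderate tree counts
# keep the suite quick; the pipeline's structure is unchanged).
default_pipeline <- function() {
  if (is.null(.cache$pipe)) {
    .cache$pipe <- run_pm25_pipeline(n_trees = 150, seed = 1)
  }
  .cache$pipe
}

expect_prob_vector <- function(v, n = NULL, tol = 1e-9) {
  if (!is.null(n)) expect_length(v, n)
  expect_true(all(v >= 0))
  expect_equal(sum(v), 1, tolerance = tol)
}
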