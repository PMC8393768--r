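#' Run the full PM2.5 mortality analysis pipeline
#'
#' Convenience driver chaining every stage on one panel: endogenous welfare
#' generation, missingness + LOESS/spline imputation, split and scaling, the
#' six linear fits with specification tests, the six tree ensembles, emulated
#' importances and the grand importance matrix F = (L | M), the stacking
#' blender (W) and aggregated importances V = F W, prior/posterior weighted
#' arrays, affinity-propagation clustering, predictive manifolds with the
#' MDS ecliptic and unsupervised-OLS blend, and the two composite-index
#' Kuznets curves.
#'
#' @param config A [generator_config()] (the panel is generated from it);
#'   alternatively pass a ready `panel` and leave `config = NULL`.
#' @param panel Optional pre-built `panel_dataset`.
#' @param seed Seed threaded through every stochastic stage.
#' @param n_trees Trees per ensemble/blender (500 mirrors the study
#'   conditions; smaller values speed exploratory runs).
#' @param tune If `TRUE`, run [grid_search_cv()] with [default_grid()] per
#'   ensemble (slow); otherwise fit with per-model defaults.
#' @param manifold_methods Embedding methods used for predictive manifolds.
#' @return A list with every intermediate object (see names).
#' @export
run_pm25_pipeline <- function(config = generator_config(), panel = NULL,
                              seed = 1L, n_trees = 500, tune = FALSE,
                              manifold_methods = c("pca", "mds", "tsne",
                                                   "isomap", "lle",
                                                   "factor")) {
  if (is.null(panel)) panel <- generate_panel(config)
  if (is.null(panel$welfare))
    panel <- generate_endogenous_welfare(panel, seed = seed)
  if (!any(panel$missing_mask)) panel <- inject_missingness(panel, seed = seed)
  imp <- impute_panel(panel)
  panel <- imp$panel
  split <- scaled_split(panel, seed = seed)

  linear_fits <- list(
    fit_pooled_ols(split),
    fit_fixed_effects(split, entity = TRUE, time = FALSE),
    fit_fixed_effects(split, entity = FALSE, time = TRUE),
    fit_fixed_effects(split, entity = TRUE, time = TRUE),
    fit_random_effects(split),
    fit_iv2sls(split))
  names(linear_fits) <- vapply(linear_fits, `[[`, character(1), "model_id")
  spec_tests <- specification_tests(linear_fits$fee, linear_fits$re,
                                    linear_fits$pooled_ols, split)

  ensemble_fits <- lapply(ENSEMBLE_IDS, function(id) {
    params <- if (tune)
      grid_search_cv(id, default_grid(id, ncol(split$X_train)),
                     split$X_train, split$y_train, seed = seed)$best_params
    else list(n_trees = n_trees, n_estimators = n_trees)
    fit_ensemble(id, split, params, seed = seed)
  })
  names(ensemble_fits) <- ENSEMBLE_IDS

  L <- do.call(cbind, lapply(linear_fits, function(f)
    as.numeric(emulate_importances(f$beta, f$pvalues))))
  rownames(L) <- names(linear_fits[[1]]$beta)
  colnames(L) <- names(linear_fits)
  M <- vapply(ensemble_fits, function(f) f$importances,
              numeric(ncol(split$X_train)))
  F_mat <- concat_importance_matrix(
    importance_matrix(L, provenance = rep("emulated", ncol(L))),
    importance_matrix(M, provenance = rep("actual", ncol(M))))

  level0 <- assemble_level0(c(linear_fits, ensemble_fits))
  blender <- fit_blender(level0, split$y_train, y_test = split$y_test,
                         seed = seed, n_trees = n_trees)
  V <- aggregate_importances(F_mat, blender$W)

  prior <- weight_columns(split$full_scaled_X)
  posterior <- weight_columns(split$full_scaled_X, as.numeric(V),
                              tag = "posterior")
  country_prior <- aggregate_by_country(prior, split$entity)
  country_posterior <- aggregate_by_country(posterior, split$entity)
  clusters <- list(
    country_prior = cluster_affinity(country_prior),
    country_posterior = cluster_affinity(country_posterior))

  manifolds <- lapply(manifold_methods, function(m)
    predictive_manifold(posterior, m, split$full_scaled_y, seed = seed))
  names(manifolds) <- manifold_methods
  ecliptic <- mds_ecliptic(posterior, split$full_scaled_y, seed = seed)
  blend <- unsupervised_ols_blend(c(manifolds, list(ecliptic)),
                                  split$full_scaled_y)

  econ_index <- composite_index(posterior, "economic", split$entity)
  health_index <- composite_index(posterior, "health", split$entity)
  mortality <- drop(aggregate_by_country(matrix(split$full_scaled_y),
                                         split$entity))
  kuznets <- list(
    economic = kuznets_curves(econ_index, mortality),
    health = kuznets_curves(health_index, mortality))

  list(panel = panel, imputation = imp$report, split = split,
       linear_fits = linear_fits, spec_tests = spec_tests,
       ensemble_fits = ensemble_fits, F_matrix = F_mat, level0 = level0,
       blender = blender, V = V, prior = prior, posterior = posterior,
       clusters = clusters, manifolds = manifolds, ecliptic = ecliptic,
       unsupervised_ols = blend, econ_index = econ_index,
       health_index = health_index, country_mortality = mortality,
       kuznets = kuznets)
}
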