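# Internal helpers shared across modules.

#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

# Population (1/n) standard deviation; the scaling convention used throughout.
#' @noRd
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Standardize to mean 0, population sd 1.
#' @noRd
standardize <- function(x) {
  s <- pop_sd(x)
  if (s == 0) stop("cannot standardize a constant vector")
  (x - mean(x)) / s
}

#' @noRd
assert_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what), call. = FALSE)
  invisible(x)
}

# The 23 panel features in canonical order, with economic/health group tags.
#' @noRd
pm25_feature_names <- function() {
  c("expectancy", "poverty_threshold", "poverty_excluded", "poverty_included",
    "emissions", "exposure", "cardio_incidence", "ischemic_incidence",
    "copd_incidence", "asthma_incidence", "tracheal_incidence", "cardio_death",
    "ischemic_death", "copd_death", "asthma_death", "tracheal_death",
    "real_gdp_pc", "health_expenditures", "environmental_taxes",
    "social_contributions", "spending", "corruption", "gini")
}

#' Feature group map (economic vs health-based)
#'
#' Tags each of the 23 panel features as `"economic"` (11 variables: the three
#' poverty measures, emissions, GDP per capita, health expenditures,
#' environmental taxes, social contributions, government spending, corruption
#' perception and the Gini index) or `"health"` (12 variables: life
#' expectancy, PM2.5 exposure, and the five disease incidence plus five
#' disease mortality series).
#'
#' @return Named character vector over the 23 features with values
#'   `"economic"` or `"health"`.
#' @export
#' @examples
#' table(pm25_group_map())
pm25_group_map <- function() {
  econ <- c("poverty_threshold", "poverty_excluded", "poverty_included",
            "emissions", "real_gdp_pc", "health_expenditures",
            "environmental_taxes", "social_contributions", "spending",
            "corruption", "gini")
  feats <- pm25_feature_names()
  setNames(ifelse(feats %in% econ, "economic", "health"), feats)
}

# EU-27 member states, the default panel entities.
#' @noRd
eu27_countries <- function() {
  c("Austria", "Belgium", "Bulgaria", "Croatia", "Cyprus", "Czechia",
    "Denmark", "Estonia", "Finland", "France", "Germany", "Greece",
    "Hungary", "Ireland", "Italy", "Latvia", "Lithuania", "Luxembourg",
    "Malta", "Netherlands", "Poland", "Portugal", "Romania", "Slovakia",
    "Slovenia", "Spain", "Sweden")
}
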