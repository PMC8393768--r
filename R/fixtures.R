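#' Reference tables shipped with the package
#'
#' Loads the published reference tables for the EU-27 PM2.5 mortality
#' analysis that this package reimplements. Four tables are available:
#'
#' * `"linear_parameters"`: beta coefficients of the six linear models
#'   (pooled OLS, FEE, FTE, FETE, RE, IV2SLS) on the 23 features, with
#'   significance codes (`***` p<0.001, `**` p<0.01, `*` p<0.05, `+` p<0.1).
#'   The IV2SLS `exposure` row carries the coefficient on the instrumented
#'   welfare variable, reported under the instrument's label.
#' * `"ml_importances"`: impurity-based feature importances of the six tree
#'   ensembles (each column a probability vector over the 23 features).
#' * `"emulated_importances"`: emulated feature importances of the six linear
#'   models (the \eqn{|\beta|(1-p)^\gamma} transform, renormalized).
#' * `"kuznets_economic"`: the 27 country-level (economic index, PM2.5
#'   mortality z-score) pairs behind the economic environmental Kuznets curve.
#'
#' @param name Which table to load.
#' @return A `data.frame`; the first column identifies the variable or
#'   country, remaining columns are numeric (plus significance-code columns
#'   for `"linear_parameters"`).
#' @export
#' @examples
#' imp <- pm25_reference_table("ml_importances")
#' colSums(imp[, -1])
pm25_reference_table <- function(name = c("linear_parameters", "ml_importances",
                                          "emulated_importances",
                                          "kuznets_economic")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("table_", name, ".csv"),
                      package = "pm25ekc", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

# Importance-matrix view of a reference table: rows = 23 features,
# columns = models, as an importance_matrix object.
#' @describeIn pm25_reference_table The `"ml_importances"` or
#'   `"emulated_importances"` table as an [importance_matrix()], renormalized
#'   column-wise (printed columns sum to 1 only up to rounding).
#' @param provenance Provenance tag for the columns, `"actual"` or `"emulated"`.
#' @export
pm25_reference_importances <- function(name = c("ml_importances",
                                                "emulated_importances"),
                                       provenance = NULL) {
  name <- match.arg(name)
  tab <- pm25_reference_table(name)
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab$variable
  m <- sweep(m, 2, colSums(m), "/")
  if (is.null(provenance)) {
    provenance <- if (name == "ml_importances") "actual" else "emulated"
  }
  importance_matrix(m, provenance = rep(provenance, ncol(m)))
}
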