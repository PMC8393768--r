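# pm25ekc

Panel econometrics, ensemble learning and environmental Kuznets curves for
premature PM2.5 mortality.

## The problem

Premature mortality attributable to fine particulate matter (PM2.5) in a
country-year panel — 27 countries, 11 years, 23 socioeconomic and
health-based predictors — can be analysed with classical panel econometrics
(pooled OLS, fixed and random effects, instrumental variables) or with
tree-ensemble regression (random forests, extra trees, AdaBoost, gradient
boosting, XGBoost, a LightGBM-style booster). The two families speak
different interpretive languages: coefficients and p-values on one side,
impurity-based feature importances on the other. `pm25ekc` implements a
pipeline that harmonizes them and pushes the harmonized result through
unsupervised learning, for epidemiologists and environmental economists who
want a single feature-weighting to drive clustering, dimensionality
reduction and Kuznets-curve construction.

## The method

1. **Emulated feature importances.** Each linear model's beta coefficients
   and p-values are translated into the probability-vector language of tree
   models:

   f_v = |β_v| (1 − p_v)^γ / Σ_j |β_j| (1 − p_j)^γ,  γ = 2 by default.

2. **Stacking generalization.** The six linear fits (emulated importances,
   matrix **L**, 23 × 6) and six ensemble fits (actual importances, matrix
   **M**, 23 × 6) are concatenated into the grand matrix **F** = (**L** |
   **M**). Their predictions form a level-0 matrix on which a tree-ensemble
   blender (extra trees by default) is trained; the blender's own
   importances, a probability vector **W** over the 12 models, weight the
   columns of **F**: the aggregated importance vector is **V** = **F W**
   (23 × 1, sums to 1 by construction).

3. **Predictive unsupervised learning.** **V** rescales the columns of the
   full scaled 297 × 23 array ("posterior", accuracy-weighted array, vs the
   "prior" equally weighted one). Affinity propagation clusters countries;
   six dimensionality-reduction methods (PCA, metric MDS, t-SNE, isomap,
   LLE, factor analysis) each compress the array to one standardized,
   sign-aligned vector — a *predictive manifold* — plus an "MDS ecliptic"
   (the plane of the first two of three MDS dimensions) and a final
   unsupervised-OLS blend of all of them.

4. **Environmental Kuznets curves.** PCA decomposes the 11 economic or the
   12 health-based columns of the posterior array into a one-dimensional
   composite index per country; polynomial fits of degree 1–4 of country
   mortality on the index (and the average of the degree 2–4 curves) display
   the canonical monotone / inverted-U / N shapes.

Because the assembled EU-27 panel is not publicly deposited, the package
includes a first-class synthetic-panel generator (`generate_panel()`)
whose defaults emulate the study conditions — 297 rows, two latent
factors with AR(1) persistence, entity effects and a year trend, an
endogenous welfare variable calibrated to correlations 0.940138 (with
mortality) and 0.769063 (with exposure), and the 54/2/3 missingness
pattern filled by LOESS + polynomial-spline imputation — so every stage is
testable end to end. The published reference tables (linear parameters,
both importance tables, the economic Kuznets pairs) ship as plain-text
fixtures (`pm25_reference_table()`).

## Worked example

```r
library(pm25ekc)
res <- run_pm25_pipeline(n_trees = 300, seed = 1)

res$linear_fits$pooled_ols
#> linear_fit [pooled_ols]: 23 coefficients
#>   train: rmse 0.1509  r2 0.9772  mbe -0.0000  wioa 0.9942
#>   test:  rmse 0.4558  r2 0.8183  mbe -0.0653  wioa 0.9452

res$blender
#> blender_fit [extra_trees, insample]: 12 stacked models
#>   W diversity: gini 0.293311  simpson 0.106368  1/simpson 9.401325
#>   train: rmse 0.0344  r2 0.9988  mbe -0.0018  wioa 0.9997
#>   test:  rmse 0.4507  r2 0.8223  mbe -0.0663  wioa 0.9428

round(sort(res$V, decreasing = TRUE)[1:5], 4)
#>         exposure   ischemic_death     cardio_death cardio_incidence
#>           0.3933           0.1452           0.1241           0.0566
#>       expectancy
#>           0.0512

res$unsupervised_ols
#> manifold_prediction [unsupervised_ols]: rmse 0.4376  r2 0.8085  mbe +0.0000  wioa 0.9502

res$clusters$country_posterior
#> cluster_solution: 4 clusters over 27 points (57 iterations)
```

Reading the output: pooled OLS explains ~98% of training variance and ~82%
of held-out variance on this synthetic draw (the gap is mostly the 54
imputed exposure cells). The extra-trees blender distributes its weight
over the equivalent of 9.4 of the 12 stacked models (reciprocal Simpson) —
the same order as the 9.16 reported for the original data. Exposure
dominates the aggregated importance vector **V**, followed by the
ischemic/cardiovascular mortality indicators, and the unsupervised-OLS
composite of eight manifold predictions tracks observed mortality almost
as well as the supervised models, which is the pipeline's central claim.

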