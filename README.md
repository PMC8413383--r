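# scenpred

Scenario-based predictive analytics for community health outcomes.

`scenpred` is an R implementation of a multi-level scenario-based
predictive analytics framework for grouped community data. It was built
for a question of the form: *how would the share of adults in a
metropolitan community reporting sustained poor mental health (`K`, a
percentage) change if the built environment around them changed* —
if poverty rose one standard deviation, if fewer families had health
insurance, if housing vacancy climbed? The same machinery applies to any
continuous community-level outcome with tagged predictors and a grouping
key (here: US states).

The framework has three stages, each exposed as ordinary functions and
orchestrated by `run_pipeline()`:

1. **Model selection.** A library of interpretable learners — GLM,
   ridge, lasso, GAM, four MARS variants, random forest, gradient
   boosting, and Bayesian additive regression trees (BART, the
   sum-of-trees model $Y = \sum_{j=1}^m g(X; T_j, M_j) + \varepsilon$,
   $\varepsilon \sim N(0, \sigma^2)$) — is compared by repeated
   randomized 80–20 holdout on $R^2$, RMSE and MAE against a null
   (training-mean) baseline, and the learner with the lowest mean
   out-of-sample RMSE is selected.
2. **Interpretation.** Variable-importance rankings (split inclusion
   proportions for tree ensembles, permutation importance otherwise)
   and partial dependence plots
   $p_j(x_j) = \frac{1}{n}\sum_{i=1}^n f(x_j, x_{-j,i})$
   with 95% bands (posterior for BART, bootstrap otherwise).
3. **Scenario projection.** Per state, parametric distributions are
   fitted to the perturbable predictors by the method of moments with
   chi-squared goodness-of-fit family selection; their means are
   shifted by ±1σ per a hypothesis sign map (H1–H10: economic
   degradation/improvement, insurance availability/type, travel cost,
   vacancy); coupled resampling through the selected model yields per
   state $\Delta K = K_{\text{scenario}} - K_{\text{base}}$ and
   $\Delta\kappa = \Delta K / K_{\text{base}} \times 100\%$, and the
   scenario is classified **worst-case** (national mean $\Delta K > 0$)
   or **best-case** (mean $\Delta K < 0$).

Correlated pre-clinical control variables are reduced to principal
components (smallest set reaching 92% cumulative variance by default)
before modelling. A synthetic-data generator with known ground truth
(`generate_communities()`) makes the whole pipeline testable without
any external data.

## Worked example

```r
library(scenpred)

gen <- generate_communities(generator_config(
  n_groups = 20, communities_per_group = c(8, 20), seed = 42))
red <- reduce_preclinical(gen$table, 0.92)
red$reduction
#> pca_reduction: 12 pre-clinical columns -> 3 components (96.2% var, threshold 92%)

specs <- lapply(c("glm", "gam", "random_forest", "gbm"),
                function(f) model_spec(f, seed = 42, label = f))
plans <- make_splits(n_communities(red$table), repeats = 10, seed = 42)
cv <- run_cv(red$table, specs, plans)
cv
#> cv_report: 4 models x 10 repeats on n=253
#>          model     r2 rmse_in mae_in rmse_out mae_out
#>            glm 0.8348  0.4424 0.3458   0.4417  0.3504
#>            gam 0.8561  0.4122 0.3224   0.4522  0.3583
#>  random_forest 0.9408  0.2725 0.2161   0.6164  0.5000
#>            gbm 0.9680  0.1633 0.1253   0.5786  0.4581
#>           null     NA  1.0842 0.8868   1.0660  0.8740
```

The generator's default response surface is essentially additive, so
the linear model generalizes best here (out-of-sample RMSE 0.44 against
a null baseline of 1.07) even though the tree ensembles fit the
training data more closely — exactly the in-/out-of-sample gap the
repeated holdout is there to expose. Interpreting the selected model:

```r
fit <- fit_model(select_best(cv), red$table)
compute_pdp(fit, red$table, "poverty", grid = c(10, 20, 30))
#>   grid effect
#> 1   10 12.457
#> 2   20 13.319
#> 3   30 14.181
```

As the share of families below the poverty line sweeps from 10% to 30%,
the expected share of adults reporting poor mental health climbs from
about 12.5% to 14.2% — a partial effect of ≈ 0.086 per poverty point
(the generating truth is 0.08 plus correlated-control leakage). The
economic-degradation scenario (poverty and unemployment up 1σ, income
down 1σ, per state):

```r
fits <- fit_group_distributions(red$table,
          c("poverty", "unemployment_change", "median_income"))
h <- default_scenarios(list(poverty = "poverty",
                            unemployment = "unemployment_change",
                            income = "median_income"), n_draws = 500)
adjudicate(run_scenario(fit, red$table, h$H1, fits, master_seed = 42),
           h$H1)
#> H1: economic degradation degrades community mental health
#>   national mean delta K = +0.7087 -> worst-case; hypothesis supported (20/20 groups conform)
```

Every state's projected `K` rises (mean +0.71 percentage points), so
the hypothesis that economic degradation worsens community mental
health is supported nationally and the scenario is classified
worst-case. Per-state `K_base`, `K_scenario`, `delta_K` and
`delta_kappa` live in the returned table.

There is also a thin CLI over the same functions:

```sh
Rscript inst/cli/scenpred.R run --out myrun --seed 42 --repeats 10
Rscript inst/cli/scenpred.R generate --out mydata --groups 50
```

## Package layout

- `R/feature-table.R`, `R/pca.R` — data model, validation, reduction
- `R/model-spec.R`, `R/fit.R`, `R/mars.R`, `R/bart.R` — the model library
- `R/selection.R` — splits, scoring, repeated-holdout harness, selection
- `R/pdp.R` — partial dependence, bands, importance ranking
- `R/distributions.R`, `R/scenario.R` — the scenario engine
- `R/synthetic.R` — the ground-truth generator
- `R/pipeline.R`, `inst/cli/scenpred.R` — orchestration and CLI
- `vignettes/scenario-analytics.Rmd` — the methods vignette
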