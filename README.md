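# pensel — penalized linear regression for biomarker selection

`pensel` is an R package for variable selection when a continuous outcome
is regressed on moderately many, partly correlated covariates (n > p) —
the situation of birth-cohort biomarker studies where a few dozen stool,
serum, anthropometric and socioeconomic predictors compete to explain a
child-growth outcome such as the height-for-age z-score (HAZ) at one year,
and where a block of them (expenditure, income, maternal anthropometry,
early growth z-scores) is strongly mutually correlated.

It implements, from a single coordinate-descent core:

* **Penalized least squares** minimizing
  `(1/2n)·||y − Xβ||² + Σⱼ p_λ(|βⱼ|)` with the **LASSO**, **Elastic Net**
  (`λ[α|β| + (1−α)β²]`), **SCAD** (`a = 3.7`), **MCP** (`a = 3`) and
  **Adaptive LASSO** (`wⱼ = |β̃ⱼ|^(−γ)` from an OLS pilot) penalties,
  with exact-zero coefficients — selection *is* sparsity;
* **BIC tuning** along a warm-started λ path:
  `BIC(λ) = n·log(RSS/n) + log(n)·df`, ties broken toward sparser models;
  for the Elastic Net, α ∈ {0.1, …, 0.9} is grid-searched jointly with λ;
* a bidirectional **stepwise** baseline and the **oracle** (OLS on the
  true support) and **full-OLS** reference estimators;
* the **simulation study** comparing all methods on AR(1)-correlated
  Gaussian designs (n = 500, p = 33, block of 8, ρ ∈ {0.2, 0.5, 0.8},
  SNR ∈ {1, 3, 5}, 100 replicates) by **MRME** (median over replicates of
  `ME(θ̂)/ME(θ̂_LS)` × 100, with `ME(θ̂) = (θ̂−θ)'Σ(θ̂−θ)`), **TP** and
  **FP**;
* **bootstrap selection-stability** reports (per-variable sign and
  selection frequency over 100 refitted resamples);
* a **synthetic cohort generator** emulating the motivating 33-biomarker
  table (published means/SDs, AR(1) ρ = 0.5 block of 8, HAZ-like outcome
  with mean −1.47, SD 1.02, SNR 2.6), so every stage runs without any
  external data.

All user-facing functions take a data frame first and return tibbles (or
objects with `tidy()`/`glance()`/`autoplot()` methods), so stages compose
with the pipe.

## Worked example

Generate a synthetic cohort, select biomarkers with BIC-tuned SCAD, and
check the stability of the selection under bootstrap resampling:

```r
library(pensel)

cohort <- generate_cohort(n = 512, seed = 11)
fit <- select_by_bic(cohort, "haz_1y", family = "scad")
dplyr::filter(tidy(fit$best_fit), selected)
#> # A tibble: 7 × 3
#>   term                   estimate selected
#>   <chr>                     <dbl> <lgl>
#> 1 mother_weight         0.0354    TRUE
#> 2 HAZ_wk18              0.739     TRUE
#> 3 MPO_wk12             -0.0000101 TRUE
#> 4 mannitol_wk12       -11.8       TRUE
#> 5 ferritin_wk6         -0.00150   TRUE
#> 6 scd14_wk18           -0.000133  TRUE
#> 7 breast_feeding_wk18  -0.00721   TRUE
```

BIC-tuned SCAD recovers exactly the seven generating effects of the
default schema (coefficients are on the native covariate scales, hence
their very different magnitudes — mannitol is measured in tiny units, MPO
in tens of thousands). Their stability under 100 bootstrap refits, for
two methods side by side:

```r
rep_scad   <- bootstrap_selection(cohort, "haz_1y", "scad", n_boot = 100, seed = 7)
rep_alasso <- bootstrap_selection(cohort, "haz_1y", "adaptive_lasso", n_boot = 100, seed = 7)
render_selection_table(list(rep_scad, rep_alasso))
#> # A tibble: 7 × 3
#>   variable            scad     adaptive_lasso
#>   <chr>               <chr>    <chr>
#> 1 mother_weight       + (1.00) + (1.00)
#> 2 HAZ_wk18            + (1.00) + (1.00)
#> 3 MPO_wk12            - (0.99) - (0.99)
#> 4 mannitol_wk12       - (1.00) - (1.00)
#> 5 ferritin_wk6        - (1.00) - (1.00)
#> 6 scd14_wk18          - (0.99) - (1.00)
#> 7 breast_feeding_wk18 - (1.00) - (1.00)
```

Every cell shows the full-data coefficient sign and, in parentheses, the
fraction of resamples reselecting the variable — all seven effects are
reselected in ≥ 99% of resamples at this signal-to-noise ratio.

One cell of the simulation study (ρ = 0.5, SNR = 3, 100 replicates):

```r
cfg <- sim_config(rho = 0.5, snr = 3, n_reps = 100, seed = 1,
                  methods = c("stepwise", "lasso", "scad",
                              "adaptive_lasso", "oracle"))
run_study(cfg)$summary
#> # A tibble: 5 × 7
#>     rho   snr method          mrme    tp    fp n_fail
#>   <dbl> <dbl> <chr>          <dbl> <dbl> <dbl>  <int>
#> 1   0.5     3 stepwise        26.4  7     0.26      0
#> 2   0.5     3 lasso           79.1  7     1.48      0
#> 3   0.5     3 scad            33.4  6.99  0.47      0
#> 4   0.5     3 adaptive_lasso  31.7  7     0.39      0
#> 5   0.5     3 oracle          19.4  7     0         0
```

MRME is the median model error relative to the full OLS fit (×100; the
oracle brackets the methods from below, full OLS is 100 by definition);
TP/FP count correctly and incorrectly selected variables out of 7 true
and 26 null effects. The LASSO's higher FP and MRME against the
near-oracle behaviour of SCAD and the Adaptive LASSO is the expected
oracle-property pattern. See `vignette source in vignettes/` for the
methodology, the role of the truth-vector shape, and all numerical
choices.

A thin command-line front end over the same functions is installed at
`inst/cli/pensel` (subcommands `simulate`, `fit`, `stability`,
`cohort-synth`; every CSV output carries a provenance header with the
config and seed).

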