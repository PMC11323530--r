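# swhte

Power and sample-size calculation for detecting **treatment-effect
heterogeneity** (a treatment-by-covariate interaction) in cross-sectional
**stepped-wedge cluster randomized trials** with binary outcomes.

Trials in healthcare-delivery and disparity research often need to show not
that an intervention helps on average, but that it helps a disadvantaged
subgroup *more* — for instance that a clinical decision-support alert raises
goals-of-care conversation rates faster among minority patients than among
others. That question is a test of the interaction between treatment and a
patient-level covariate, and it needs far larger samples than the average
effect. `swhte` provides the design-stage machinery for this setting, plus a
full simulation loop to verify the predictions.

## Model and methods

The outcome of individual *k* in cluster *i* at period *j* follows the
marginal logistic model

    logit(mu_ijk) = theta0 + gamma_j + theta1 * W_ij + theta2 * X_ijk
                    + theta3 * W_ij * X_ijk

with treatment indicator `W` (uni-directional crossover), binary covariate
`X`, overall treatment effect `theta1` (OTE) and interaction `theta3` (HTE),
all on the log odds-ratio scale. Within-cluster correlation is block
exchangeable: ICC `alpha` within a period, `alpha * rho` across periods
(CAC `rho`; `rho = 1` is simple exchangeable).

The design-stage variance of the GEE interaction estimator is approximated
by the model-based form `(sum_i M_i' Sigma_i^{-1} M_i)^{-1}` (**GEE**), and
by bias-corrected sandwich forms with leverage-based residual modifications
`(I - H_i)^{-1/2}` (**GEE-KC**, Kauermann–Carroll) and `(I - H_i)^{-1}`
(**GEE-MD**, Mancl–DeRouen). Predicted power for the two-sided Wald test of
`H0: theta3 = 0` against `theta3 = delta` is

    power = Phi( delta / sqrt(Var(theta3_hat)) - z_{1 - alpha/2} )

with a t-based analogue (df = I − 4 by default) for small numbers of
clusters. A Gaussian-copula generator produces correlated binary outcomes
with exactly these marginal means and correlations, and a Fisher-scoring
GEE fitter with naive, robust, KC and MD empirical standard errors closes
the loop for empirical type-I-error and power studies.

## Worked example

Planned goals-of-care trial: 8 practices, 5 periods, 15 patients per
practice-period, minority prevalence 1/3, control conversation rates 35%
(non-minority) and 15% (minority) hypothesised to rise to 40% and 30%,
ICC 0.1, CAC 0.8, t-based test:

```r
library(swhte)
goc <- sw_design(
  n_clusters = 8, n_periods = 5, cluster_size = 15, p_covariate = 1 / 3,
  theta0 = log(0.35 / 0.65), gammas = rep(0, 5),
  theta1 = log(1.24), theta2 = log(0.33), theta3 = log(1.96),
  icc = 0.1, cac = 0.8, test = "wald_t"
)
sw_power(goc)[, c("method", "cluster_size", "se_hte", "predicted_power")]
#> # A tibble: 3 × 4
#>   method cluster_size se_hte predicted_power
#>   <chr>         <int>  <dbl>           <dbl>
#> 1 GEE              15  0.394           0.172
#> 2 GEE-KC           15  0.428           0.147
#> 3 GEE-MD           15  0.466           0.127

sw_find_cluster_size(goc, 0.8)
#> # A tibble: 3 × 4
#>   method cluster_size target_power predicted_power
#>   <chr>         <int>        <dbl>           <dbl>
#> 1 GEE              81          0.8           0.812
#> 2 GEE-KC           96          0.8           0.806
#> 3 GEE-MD          117          0.8           0.809

sw_find_mde(goc, 0.8)
#> # A tibble: 3 × 4
#>   method mde_or target_power predicted_power
#>   <chr>   <dbl>        <dbl>           <dbl>
#> 1 GEE      4.24          0.8           0.800
#> 2 GEE-KC   4.8           0.8           0.800
#> 3 GEE-MD   5.51          0.8           0.800
```

Reading: at the planned size the study has only ~17% power (GEE; less under
the conservative corrections) for the interaction. Reaching 80% power needs
81 patients per practice-period under GEE (117 under MD), or — at the
planned 15 — an interaction odds ratio of 4.24 (GEE), more than twice the
hypothesised 1.96.

Simulation-based validation of any design:

```r
d <- load_sw_config(system.file("extdata", "table1.yaml", package = "swhte"))$design
sw_operating_characteristics(d, n_reps = 1000, seed = 1)   # phi0 / psi0, SE bias
```

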