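---
title: "Power for treatment-effect heterogeneity in stepped-wedge trials: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Power for treatment-effect heterogeneity in stepped-wedge trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swhte)
```

## The design problem

A cross-sectional stepped-wedge cluster randomized trial (SW-CRT) enrols
`I` clusters over `J` periods; every cluster starts in the control
condition and crosses to the intervention at a staggered, randomized time,
so that by the last period all clusters are treated. In each period a fresh
sample of `m` individuals is measured per cluster (cross-sectional design —
no repeated measures on a person). Trials aimed at reducing disparities in
care are typically not powered for the *average* effect of the
intervention but for the question of whether the intervention helps one
subgroup (say, minority patients) more than another: the
treatment-by-covariate interaction, here called the heterogeneity of
treatment effect (HTE).

`swhte` computes design-stage power and sample size for testing that
interaction when the outcome is binary, and validates the predictions by
full-cycle simulation (generate correlated binary data, fit the model,
test, repeat).

## Marginal model

The binary outcome \(Y_{ijk}\) of individual \(k\) in cluster \(i\) at
period \(j\) follows the marginal (population-averaged) logistic model

\[
\mathrm{logit}(\mu_{ijk}) \;=\; \theta_0 + \gamma_j + \theta_1 W_{ij}
  + \theta_2 X_{ijk} + \theta_3 W_{ij} X_{ijk},
\]

where \(W_{ij}\) indicates treatment, \(X_{ijk}\) is an individual binary
covariate (e.g. minority race), \(\theta_1\) is the overall treatment
effect (OTE) and \(\theta_3\) the HTE, both log odds ratios;
\(\gamma_1 = 0\) for identification. The parameter vector has \(J + 3\)
components and the HTE is always its last element.

Within-cluster dependence is block exchangeable: outcomes of two
individuals in the same cluster and period are correlated \(\alpha\) (the
intraclass correlation, ICC), outcomes in different periods are correlated
\(\alpha\rho\), where \(\rho\) is the cluster autocorrelation (CAC).
\(\rho = 1\) gives the simple exchangeable structure; \(0 < \rho < 1\)
the nested exchangeable structure. The implied correlation matrix
\(R(\alpha, \rho)\) has three distinct eigenvalues,
\(1-\alpha\), \(1-\alpha+m\alpha(1-\rho)\) and
\(1-\alpha+m\alpha(1-\rho)+Jm\alpha\rho\); admissibility (all three
positive) is checked eagerly when a design is constructed, and the
spectral form gives a closed-form inverse used everywhere.

## Variance approximations and power

Solving the GEE for this model, the covariance of the estimator is
approximated at the design stage (no data involved) by the model-based
form

\[
\widetilde{\mathrm{Var}}(\hat\Theta) =
  \Big(\sum_i M_i^\top \Sigma_i^{-1} M_i\Big)^{-1},
\qquad \Sigma_i = A_i^{-1/2} R_i A_i^{-1/2},
\]

with \(M_i\) the stacked individual-level design matrix, \(A_i\) the
Bernoulli variance diagonal evaluated at the assumed coefficients. This
form is known to understate the true sampling variance when `I` is small.
Two standard leverage corrections are therefore offered, both expressible
as the three-factor sandwich with middle term
\(\sum_i M_i^\top \Omega_i^{-1} M_i\) and residual-modification matrix
\(F_i\) acting through the cluster leverage
\(H_i = A_i M_i (\sum M^\top\Sigma^{-1}M)^{-1} M_i^\top \Sigma_i^{-1}A_i^{-1}\):

* **GEE** — \(F_i = I\); the sandwich collapses exactly to the model-based
  form (an identity the test suite checks to 1e-10);
* **GEE-KC** (Kauermann–Carroll) — \(F_i = (I - H_i)^{-1/2}\);
* **GEE-MD** (Mancl–DeRouen) — \(F_i = (I - H_i)^{-1}\).

Predicted power for the two-sided Wald test of \(H_0 : \theta_3 = 0\)
against \(\theta_3 = \delta\) is

\[
\varphi = \Phi\!\Big(\delta \big/ \sqrt{\widetilde{\mathrm{Var}}(\hat\theta_3)}
  - z_{1-\alpha/2}\Big),
\]

with a t-based analogue (`test = "wald_t"`) that replaces both the
distribution function and the critical value by t counterparts. The
variance ordering GEE \(\le\) KC \(\le\) MD makes GEE the most optimistic
and MD the most conservative sample-size recommendation.

## Numerical strategy for the corrections

\(H_i\) is a \(Jm \times Jm\) non-symmetric matrix (3600 entries per
cluster at `m = 120` per period would be 600×600), but it has rank at most
\(J+3\): \(H_i = U_i C_i^\top\) with \(U_i = A_i M_i\) and
\(C_i^\top = B^{-1} M_i^\top \Sigma_i^{-1} A_i^{-1}\). Any analytic
function of \(I - H_i\) therefore reduces to
\(I + U_i\,\phi(S_i)\,C_i^\top\) with \(S_i = B^{-1} B_i\) a
\((J+3)\times(J+3)\) matrix (\(B_i\) the cluster information, \(B\) the
total) and \(\phi(x) = (f(1-x)-1)/x\): \(\phi_{KC}(x) = ((1-x)^{-1/2}-1)/x\),
\(\phi_{MD}(x) = 1/(1-x)\). Carrying this reduction through the sandwich
gives an expression in \((J+3)\)-dimensional blocks only, so the full
KC/MD covariance for any cluster size costs microseconds and is *exact* —
no truncation is involved. \(S_i\) is similar to a symmetric positive
semidefinite matrix, so its eigenvalues are real; designs in which a
cluster carries so much leverage that an eigenvalue reaches 1 are rejected
with an explicit error. The matrix square root in KC is the principal
root, which this reduction computes implicitly; a literal dense
transcription of the displayed formulas (explicit eigendecomposition of
\(I - H_i\)) is retained as `engine = "dense"` and the two paths are
compared to 1e-10 in the tests. Clusters sharing a crossover pattern share
all of these objects, and the structured inverse of \(R\) avoids any dense
\(Jm \times Jm\) algebra on the fast path.

## Searches

* `sw_find_cluster_size()` walks the grid `step, 2*step, …` and returns the
  first size meeting the target power. The default step is the smallest
  integer (up to 10) making `m * p_covariate` integral — 10 at 30%
  prevalence, 2 at 50%, 3 at 1/3 — so the deterministic covariate
  allocation `round(m * p)` is exact along the grid. This grid convention
  matters: at a target of 80% for the worked example below the step-3 grid
  answers 81, while a step-1 search would answer 80 with a covariate
  fraction slightly off 1/3.
* `sw_find_n_clusters()` searches multiples of `J - 1` (the balanced
  schedule constraint).
* `sw_find_mde()` brackets and bisects the HTE odds ratio, re-evaluating
  the variance at each candidate (the marginal means, hence the
  information, depend on the effect size), then returns the smallest
  multiple of the reporting resolution (default 0.01) meeting the target.

For the t-based test the default degrees of freedom are `I - 4` (clusters
minus the four cluster-level parameters), overridable via `t_df`.

## The data generator

`sw_latent()`/`sw_simulate()` implement a Gaussian copula for multivariate
binary outcomes: \(Y_{ijk} = 1\{Z_{ijk} \le \Phi^{-1}(\mu_{ijk})\}\) with
\(Z_i \sim N(0, \Xi_i)\). Each entry of the latent correlation matrix
\(\Xi_i\) solves the bivariate equation
\(\Phi_2(\Phi^{-1}(\mu_1), \Phi^{-1}(\mu_2); \xi) = \mu_1\mu_2 +
r\sqrt{v_1 v_2}\) for the target outcome correlation \(r\) (\(\alpha\)
within period, \(\alpha\rho\) between), by bracketed root search on
\([-0.9999, 0.9999]\) to 1e-8 on the joint probability, with the bivariate
normal CDF from **mvtnorm**. Infeasible targets (outside the
Fréchet–Hoeffding bounds) raise an error naming the pair. Only the
distinct (mean, mean, lag-class) combinations are solved — a cache the
tests bound explicitly — and clusters with the same crossover pattern
share one Cholesky factorization.

The assembled \(\Xi_i\) need not be positive semidefinite. When it is not,
eigenvalues are floored at 1e-6, the matrix is reconstructed and rescaled
to unit diagonal, and the event is reported via a `message()` together
with the largest entry change (in the simulation settings used here the
change is at most a few 1e-3). The floor and the rescaling rule are this
package's choices; published descriptions of the trick do not fix them.

What the generator emulates is exactly the design assumptions: equal
cluster sizes, a deterministic covariate count per cluster-period,
block-exchangeable correlation constant over time, and marginal means that
follow the model. Real trials deviate from all four (unequal and
time-varying cluster sizes, random covariate mix, correlation decaying
with time separation, calendar shocks), so agreement between predicted and
simulated power here validates the variance algebra — not the realism of
those assumptions for any particular trial.

## GEE fitting

`sw_gee()` is a Fisher-scoring solver: at each iteration the coefficient
update solves the weighted system built from the structured
\(\Sigma_i^{-1}\), then the working-correlation moments are re-estimated
from standardized Pearson residual cross-products (within-period products
give \(\hat\alpha\); cross-period products give \(\hat\alpha\hat\rho\);
the `exchangeable` working structure pools both classes and fixes
\(\rho = 1\); `independence` fixes both at zero and reproduces pooled
logistic maximum likelihood to 1e-6, an oracle the tests exercise).
Iteration stops when the largest parameter change falls below 1e-6, with a
cap of 100 iterations. Estimates outside a plausible range or fitted
probabilities collapsing to 0/1 flag the replicate as separated;
non-converged or separated replicates are excluded from
operating-characteristic denominators and reported as a count — a
transparency choice, since reference studies are silent on their handling.
Moment estimates of \(\alpha\) are clamped to the admissible region; no
degrees-of-freedom correction is applied to the moment averages (the
slight small-`I` attenuation this causes is visible in the tests'
tolerance of 0.03 around a true ICC of 0.1 and does not propagate to the
operating characteristics, which are driven by the coefficient estimates
and their naive covariance at the *estimated* correlation).

Empirical covariance estimators mirror the design-stage ones with fitted
residuals: naive (model-based), robust (uncorrected sandwich), KC and MD
(leverage-modified residuals, same low-rank reduction).

## Operating characteristics

`sw_operating_characteristics()` runs the replicate loop
simulate → fit → Wald test and reports the rejection proportion: the
empirical type I error \(\psi_0\) under a null generating value, the
simulated power \(\varphi_0\) otherwise, together with the binomial Monte
Carlo standard error, the mean reported SE minus the empirical SD of the
estimates (the SE bias), and the empirical-minus-model-based variance
difference. One `set.seed()` call at entry makes the whole run
deterministic in the seed; replicates are drawn sequentially (no parallel
path, so no substream contract is needed). `sw_reproduce_table()` drives
the published comparison tables from the same machinery.

Problem sizes used in the shipped tests are the package's own trade-off
between Monte Carlo resolution and runtime: 300 replicates for the
simulated-power check (compared through its 95% binomial interval), 1000
replicates for the type I error band [0.036, 0.064], 10,000 simulated
clusters for the copula fidelity check, and 200 replicates at
`I = 40, m = 120` for interaction recovery.

## Worked example

The motivating trial: 8 oncology practices, 5 periods, 15 advanced-cancer
patients per practice-period, outcome = documented goals-of-care
conversation, covariate = minority race (prevalence 1/3). Control rates
35% (non-minority) and 15% (minority); the intervention is hypothesised to
lift them to 40% and 30%, giving \(\theta_1 = \log 1.24\),
\(\theta_2 = \log 0.33\), \(\theta_3 = \log 1.96\); no secular trend;
ICC 0.1, CAC 0.8; t-based test with 4 degrees of freedom.

```{r example, eval = FALSE}
goc <- sw_design(
  n_clusters = 8, n_periods = 5, cluster_size = 15, p_covariate = 1 / 3,
  theta0 = log(0.35 / 0.65), gammas = rep(0, 5),
  theta1 = log(1.24), theta2 = log(0.33), theta3 = log(1.96),
  icc = 0.1, cac = 0.8, test = "wald_t"
)
sw_power(goc)                  # predicted power at m = 15: far below 80%
sw_find_cluster_size(goc, 0.8) # cluster sizes needed for 80% power
sw_find_mde(goc, 0.8)          # detectable interaction odds ratio at m = 15
```

At `m = 15` the design is severely underpowered for the interaction
(about 17% under GEE, less under the corrections); reaching 80% power
requires 81 patients per practice-period under GEE (117 under MD), or an
interaction odds ratio of 4.24 (GEE) at the planned size — the
quantitative form of the warning that interaction effects need far larger
samples than average effects.

## Known limitations

* Cross-sectional designs with equal cluster sizes only; closed- and
  open-cohort layouts, transition periods and unequal `m` are out of
  scope.
* Simple and nested exchangeable working correlations only; no
  exponential-decay structure.
* Binary outcomes and an individual-level binary covariate; no
  cluster-level covariates, continuous or censored endpoints.
* The treatment effect is immediate and constant over exposure time.
* Published reproduction note: the worked example's printed predicted
  powers could not be matched exactly under any allocation or test
  convention consistent with the rest of the published tables (the
  package's values are about half a percentage point lower), while the
  same example's required size and minimal detectable effect are matched
  exactly; the package keeps the convention that reproduces the full
  published grids and the example's design outputs.
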