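# geladjust

Nonparametric covariate adjustment for two-arm randomized trials using the
generalized empirical likelihood (GEL) family, alongside the classical
ANOVA/ANCOVA comparator, and a Monte-Carlo engine to evaluate all of them.

## Who this is for

Trialists and biostatisticians who want to adjust a continuous outcome
comparison for baseline covariates *without* assuming the linear,
homoscedastic, normal-error model that ANCOVA imposes. Randomization
guarantees that the covariates have equal means across arms; the GEL methods
exploit only that fact.

## The method

Let `y` be the outcome, `z ∈ {0,1}` the arm indicator (0 = control,
1 = intervention), and `x1..xk` baseline covariates. The estimand is the mean
difference `Δ = E[y|z=0] − E[y|z=1]`. With `θ = (μ1, Δ, μx)` the moment
conditions are

```
E[ z (y − μ1) ]              = 0
E[ (1−z)(y − μ1 − Δ) ]       = 0
E[ z (xj − μxj) ]            = 0   for j = 1..k
E[ (1−z)(xj − μxj) ]         = 0   for j = 1..k
```

— the `k` extra conditions are exactly covariate balance, the overidentifying
information that delivers the efficiency gain. A GEL estimator reweights the
observations as little as possible, as measured by a divergence `ρ` between
the new weights and the uniform `1/n`, subject to these conditions:

```
θ̂ = argmin_θ  sup_λ  (1/n) Σ_i ρ(λ′ g_i(θ))
```

with `ρ(v) = log(1−v)` (empirical likelihood, EL), `1 − e^v` (exponential
tilting, ET), or `−v − v²/2` (continuous updating, CUE). Confidence intervals
come from test inversion: the profiled LR statistic
`D(Δ0) = 2n [min_{μ1,μx} Q(θ; Δ0) − Q(θ̂)]` is compared with the χ²(1)
quantile, and the 95% interval is `{Δ0 : D(Δ0) ≤ 3.841}`.

The OLS comparator (`fit_ancova`) reports the same contrast with classical
and HC3 heteroscedasticity-robust standard errors.

## Worked example

```r
library(geladjust)

sc  <- scenario(dist = "normal", rho = 0.5, k = 2)   # null trial, n = 200
td  <- simulate_trial(sc, seed = 1)
fit <- gel_estimate(td, family = "CUE", k = 2)
fit
#> CUE covariate-adjusted fit (k = 2, n = 200)
#>       mu1     delta      mux1      mux2
#> -0.182701  0.069892 -0.123305  0.024451
#> saddle objective 3.923e-03, converged: TRUE

invert_ci(td, "CUE", k = 2, fit = fit)
#> CUE test-inversion 95% CI for the mean difference
#>   estimate 0.06989, CI (-0.15194; 0.29177)

fit_ancova(td, k = 2)
#> ANCOVA fit (k = 2, n = 200)
#>   mean difference (control - intervention): 0.06989
#>   classical 95% CI (-0.15250; 0.29228), se 0.11276
#>   HC3       95% CI (-0.15682; 0.29660), se 0.11496
```

The adjusted difference (true value 0 here) is estimated at 0.070 with a 95%
interval spanning zero; on well-behaved normal data the CUE and ANCOVA
intervals nearly coincide, which is the expected first-order equivalence. A
small Monte-Carlo run aggregates RMSE, empirical coverage of the nominal 95%
intervals, and the rejection rate of the 5% test of no effect:

```r
res <- run_simulation(sc, c("cue", "ancova"), k = 1, reps = 200, seed = 7)
aggregate_results(res, delta_true = 0)
#>   method n_reps_requested n_converged      rmse coverage rejection_rate
#> 1 ANCOVA              200         200 0.1253563     0.94           0.06
#> 2    CUE              200         200 0.1253520     0.94           0.06
```

`reproduce_table()` runs the full published table layouts, and
`analyze_dataset()` produces a Table-9-style report (estimates and 95% CIs
for `μ1`, `Δ`, and `μx` or `βx`) for any CSV with columns `y, z, x1..xk`.
A thin command-line wrapper lives at `inst/scripts/geladjust`
(`simulate`, `reproduce-table`, `analyze` subcommands).

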