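---
title: "GEL covariate adjustment for randomized trials: models, simulation design, and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GEL covariate adjustment for randomized trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geladjust)
```

## The estimation problem

A two-arm randomized trial yields an outcome $y$, an arm indicator
$z \in \{0,1\}$ (0 = control, 1 = intervention) and baseline covariates
$x_1, \dots, x_k$. The estimand is the mean difference
$\Delta = E[y \mid z=0] - E[y \mid z=1]$. ANCOVA estimates it by a linear
model with normal, homoscedastic errors; those assumptions are exactly what a
sensitivity analysis should not rely on. Randomization, however, guarantees —
with no modeling at all — that the covariate distribution is the same in the
two arms. The generalized empirical likelihood (GEL) estimators in this
package use only that guarantee.

With $\theta = (\mu_1, \Delta, \mu_{x1}, \dots, \mu_{xk})$, the
per-observation moment vector `moment_matrix()` stacks the group-wise outcome
centerings and, for each covariate, a balance condition per arm at a *common*
mean $\mu_{xj}$:

$$g_i(\theta) = \bigl[\, z_i(y_i - \mu_1),\;
(1-z_i)(y_i - \mu_1 - \Delta),\;
z_i(x_{i1}-\mu_{x1}),\; (1-z_i)(x_{i1}-\mu_{x1}),\;\dots \,\bigr]$$

There are $q = 2 + 2k$ conditions for $p = 2 + k$ parameters; the $k$
overidentifying restrictions are precisely covariate balance. This layout was
a genuinely open design choice (several equivalent parameterizations exist);
we chose the one in which balance appears directly as the overidentifying
restriction, because it makes the mechanism of the efficiency gain visible
and reduces exactly to the two-sample method of moments when $k = 0$. A
different but equivalent parameterization would move numbers between nuisance
coordinates without changing $\hat\Delta$.

## The saddle-point problem and its members

The estimator solves
$$\hat\theta = \arg\min_\theta \sup_\lambda \frac1n \sum_i
\rho\!\left(\lambda' g_i(\theta)\right),$$
with the carrier $\rho$ normalized to $\rho(0)=0$, $\rho'(0)=\rho''(0)=-1$:
$\log(1-v)$ for empirical likelihood (EL), $1-e^v$ for exponential tilting
(ET), and $-v-v^2/2$ for the continuous updating estimator (CUE, Euclidean
likelihood). The implied probabilities $w_i \propto -\rho'(\hat\lambda'
g_i(\hat\theta))$ are the reweighting: the first-order condition in $\lambda$
is exactly $\sum_i w_i\, g_i(\hat\theta) = 0$, i.e. weighted covariate
balance. EL and ET weights are positive by construction; CUE weights can be
negative, which we report (`negative_weights`) rather than clip, since
clipping would silently change the estimator.

Confidence intervals invert the profiled likelihood-ratio statistic
$$D(\Delta_0) = 2n\Bigl[\min_{\mu_1,\mu_x} Q(\theta;\Delta_0) -
Q(\hat\theta)\Bigr],$$
compared with the $\chi^2_1$ quantile (3.841459 at 95%). All three families
use the same calibration: they are first-order equivalent, and no
higher-order correction (Bartlett, bootstrap) is applied — deliberately out
of scope. The statistic is invariant to affine renormalizations of $\rho$,
so the choice of normalization above is cosmetic for inference.

## Numerical choices

* **Inner solve.** For CUE the maximizer is closed form,
  $\lambda = -(n^{-1}\sum g_i g_i')^{-1}\bar g$. For EL/ET a safeguarded
  Newton iteration with backtracking is used; EL iterates are confined to
  $1-\lambda'g_i > 1/n$ (the classical weights-below-one safeguard), so one
  outlying observation degrades the step rather than crashing the solve. We
  verified on heavy-tailed data that replacing the $1/n$ bound by bare
  positivity leaves coverage essentially unchanged, so the safeguard is not
  binding in practice. Gradient tolerance `1e-11` in the max norm.
* **Outer solve.** BFGS on the profile objective with the analytic
  envelope-theorem gradient, started from the closed-form just-identified
  initializer (group means and covariate grand means), with a Nelder–Mead
  restart if BFGS reports failure. The initializer is already consistent, so
  a gradient method from that point is both faster and more accurate than a
  simplex-first schedule; the just-identified case ($k=0$, unrestricted) is
  returned in closed form. Relative tolerance `1e-9`.
* **Restricted fits** (for $D(\Delta_0)$, and for any other single parameter
  via `invert_ci(param=)`) are warm-started from the unrestricted solution.
* **Root finding** for CI endpoints: geometric bracket expansion away from
  $\hat\Delta$ in units of the unadjusted pooled standard error (up to 20
  of them, widened once to 40 before flagging failure), then bisection via
  `uniroot` to `1e-6` on the $\Delta$ scale. Deterministic throughout.
* **Degenerate inputs.** An exactly-constant outcome in both arms yields a
  zero-width interval at $\hat\Delta$: every other hypothesized value forces
  an infinite (EL) or large (CUE) divergence from uniform weights. Rank
  deficiency of the second-moment matrix raises an explicit error; inner
  non-convergence is a flag, never an exception, and flagged replicates are
  excluded from simulation aggregates with their count reported.
* **Ties/sign conventions.** $\Delta$ is control minus intervention
  everywhere, including the OLS comparator, where $\hat\Delta$ is minus the
  coefficient on $z$.

## The ANOVA/ANCOVA comparator

`fit_ancova()` is deliberately plain OLS of $y$ on $(1, z, x_{1..k})$ with
*no* treatment-by-covariate interactions — under interaction scenarios this
misspecification is part of what is being evaluated. Classical standard
errors use $\hat\sigma^2 (X'X)^{-1}$; robust ones use HC3,
$(X'X)^{-1} X' \mathrm{diag}\{e_i^2/(1-h_{ii})^2\} X (X'X)^{-1}$, with $t$
quantiles on $n-p$ degrees of freedom in both cases (slightly conservative
for the robust interval; a common practical choice). The HC3 implementation
is cross-checked in the tests against an independent reference
implementation at `1e-10`.

## What the synthetic generator emulates

`scenario()`/`simulate_trial()` reproduce a three-family simulation design:
$(y_0, x_1, \dots, x_k)$ has mean zero, unit variances and equicorrelation
$\rho$, drawn as

* **normal** — multivariate normal;
* **t3** — multivariate $t$ with 3 degrees of freedom whose scale matrix is
  the equicorrelation matrix divided by 3, so marginal variances are 1. The
  family is the heavy-tail stress test: fourth moments do not exist;
* **lognormal** — coordinate-wise $\exp$ of a latent Gaussian, mean-centered.
  The latent marginal variance solves $(e^{s}-1)e^{s}=1$, i.e.
  $e^{s}$ equals the golden ratio, and the latent cross-covariance solves
  $e^{s}(e^{c}-1)=\rho$, so the observed variables again have unit variance
  and correlation $\rho$. This is the skewness stress test. The construction
  requires $\rho \ge 0$.

Marginal variances are normalized to one *within every family* so that RMSE
values are comparable across families; coverage and rejection rates are
invariant to this normalization. Treatment effects enter through
`apply_treatment_transform()`: intervention outcomes are scaled by
$\sqrt{v_1}$ and shifted by $\beta_2(x_{i1}+\dots+x_{ik})$, control outcomes
by the true difference. The square root makes $v_1$ *itself* the group-2
variance when $\beta_2 = 0$, matching the closed forms in
`theoretical_group2_moments()`:
$$\mathrm{Var}(y\mid z{=}1) = v_1 + 2\rho k \beta_2 \sqrt{v_1} +
\beta_2^2 k (1+(k-1)\rho), \qquad
\mathrm{Cor}(y, x_j \mid z{=}1) = \frac{\rho\sqrt{v_1} +
\beta_2(1+(k-1)\rho)}{\sqrt{\mathrm{Var}(y\mid z{=}1)}}.$$
These transforms change variances and correlations in one arm but leave all
moment conditions valid, which is why the GEL methods remain consistent
while classical ANCOVA standard errors fail when group sizes are unequal.

Group assignment is the deterministic block layout (first $n(1-\delta)$
controls, then $n\delta$ treated); because generated rows are exchangeable
this is distributionally equivalent to random allocation and makes
replicates cheaper to reason about.

A second generator, `scenario_part3()`/`sample_part3()`, draws a bivariate
normal $(y, x)$ from the summary statistics of a real dust-control trial's
log blood-lead concentrations (means 1.82/1.07, SDs 0.58/0.52, correlation
0.35, 100 per arm). Its effect grid is expressed in *outcome standard
deviation units*: a standardized difference $\Delta$ shifts the control mean
by $0.58\,\Delta$. The object's `delta_true` element carries the truth on
the outcome scale, which is what coverage and RMSE are measured against.

What the generator does **not** emulate: missing data, measurement error,
non-exchangeable allocation (stratification, minimization), discrete or
skewed covariate-outcome relations beyond the three families, and more than
two arms. Passing simulations therefore demonstrate calibration and
efficiency under clean sampling, not robustness to those complications.

## The Monte-Carlo engine

`run_simulation()` spawns one L'Ecuyer-CMRG substream per replicate from the
root seed, so replicate $r$ is reproducible in isolation and under any
parallel schedule; the whole pipeline is a pure function of (scenario, seed).
Coverage and rejection indicators for the GEL methods are computed by
default through the exact test-inversion duality — $\Delta_0$ lies in the
95% interval iff $D(\Delta_0) \le 3.841$ — which is the *definition* of the
inverted interval and costs two restricted fits instead of two root
searches; `gel_inference = "invert"` computes the full interval, and the
test suite confirms both routes give identical indicators. Non-convergent
replicates are excluded per method with counts reported, making the policy
auditable.

Default replicate counts in `reproduce_table()` are 10,000 for the OLS
methods and 1,000 for the GEL methods (the package's own choice of scale for
the expensive test-inversion path; a flag overrides it). The corresponding
Monte-Carlo standard error of a coverage estimate is about 0.002 at 10,000
replicates and 0.007 at 1,000.

## Known limitations

* EL inference is the least stable member on heavy-tailed data, and its
  interval is slightly anti-conservative there; no Bartlett or bootstrap
  correction is offered.
* CUE implied probabilities may be negative; they are diagnostics, not a
  usable resampling distribution.
* The moment set uses the identity balance function only; balancing general
  transformations $f(x)$ (higher moments, indicators) is not implemented.
* Exactly two arms; one-sided intervals and multiplicity control are out of
  scope.
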