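# Small fixtures and independent oracles used across the test files.
# Everything here is deliberately written from first principles, without
# touching the package's solver internals.

# deterministic 4-observation toy trial
toy_trial <- function() {
  trial_data(y = c(1.5, -0.5, 2.0, 0.25),
             z = c(0L, 0L, 1L, 1L),
             X = matrix(c(0.3, -1.2, 0.8, 0.1), ncol = 1))
}

random_trial <- function(n = 60, k = 2, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * k), n, k)
  z <- rep(c(0L, 1L), length.out = n)
  y <- 0.3 + 0.5 * z + X %*% rep(0.4, k) + rnorm(n)
  trial_data(drop(y), z, X)
}

# One-sample empirical log-likelihood ratio at a hypothesized mean (Owen):
# scalar multiplier found by root-finding, independent of the package solver.
owen_elr <- function(x, mu) {
  u <- x - mu
  if (min(u) >= 0 || max(u) <= 0) return(Inf)
  f <- function(t) sum(u / (1 + t * u))
  t <- uniroot(f, c(-1 / max(u) + 1e-9, -1 / min(u) - 1e-9), tol = 1e-12)$root
  2 * sum(log1p(t * u))
}

# Two-sample EL LR for the mean difference (control minus intervention),
# profiling the common location numerically.
two_sample_el_D <- function(data, delta0) {
  y1 <- data$y[data$z == 1L]
  y0 <- data$y[data$z == 0L]
  fn <- function(mu) owen_elr(y1, mu) + owen_elr(y0, mu + delta0)
  suppressWarnings(
    optimize(fn, range(c(y1, y0 - delta0)), tol = 1e-10)$objective
  )
}

# Continuous-updating GMM criterion computed by plain matrix algebra.
cu_gmm_criterion <- function(theta, data, k) {
  g <- moment_matrix(theta, data, k = k)
  gbar <- colMeans(g)
  omega <- crossprod(g) / nrow(g)
  0.5 * drop(t(gbar) %*% solve(omega, gbar))
}
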