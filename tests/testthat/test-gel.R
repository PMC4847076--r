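test_that("rho carriers satisfy the common normalization", {
  for (fam in c("EL", "ET", "CUE")) {
    sp <- rho_spec(fam)
    expect_equal(sp$rho(0), 0)
    expect_equal(sp$rho1(0), -1)
    expect_equal(sp$rho2(0), -1)
  }
})

test_that("zero mean moments give a zero multiplier for every family", {
  td <- random_trial(seed = 11)
  y1 <- mean(td$y[td$z == 1L]); y0 <- mean(td$y[td$z == 0L])
  g <- moment_matrix(c(y1, y0 - y1), td, k = 0)
  for (fam in c("EL", "ET", "CUE")) {
    s <- solve_lambda(g, fam)
    expect_equal(s$lambda, c(0, 0))
    expect_equal(s$value, 0)
    expect_true(s$converged)
  }
})

test_that("CUE multiplier equals the closed-form linear solve", {
  # 5-observation fixture, direct matrix algebra as the oracle
  g <- matrix(c(0.5, -0.2, 1.1, -0.7, 0.3,
                0.1,  0.4, -0.9, 0.2, -0.6), ncol = 2)
  s <- solve_lambda(g, "CUE")
  lam_direct <- -solve(crossprod(g) / 5, colMeans(g))
  expect_equal(s$lambda, lam_direct, tolerance = 1e-12)
  expect_equal(s$value, 0.5 * drop(crossprod(colMeans(g),
                                             solve(crossprod(g) / 5,
                                                   colMeans(g)))),
               tolerance = 1e-12)
})

test_that("EL iterates respect the likelihood domain even with an outlier", {
  set.seed(21)
  g <- matrix(c(rnorm(19, sd = 0.3), 8), ncol = 1)  # one outlying moment
  g[, 1] <- g[, 1] - mean(g[, 1]) + 0.15
  s <- solve_lambda(g, "EL")
  expect_true(all(1 - g %*% s$lambda > 0))
  # brute-force grid confirms the maximizer (over the whole EL domain)
  grid <- seq(1 / min(g) + 1e-6, 1 / max(g) - 1e-6, length.out = 20000)
  vals <- vapply(grid, function(l) mean(log1p(-g * l)), 0)
  expect_equal(s$value, max(vals), tolerance = 1e-6)
})

test_that("EL objective matches a brute-force multiplier grid on a toy", {
  g <- matrix(c(1, -1, 1, -1, 0.8), ncol = 1)  # shifted +/-1 pattern
  s <- solve_lambda(g, "EL")
  grid <- seq(-0.9, 0.9, length.out = 40001)
  vals <- vapply(grid, function(l) mean(log1p(-g * l)), 0)
  expect_equal(s$value, max(vals), tolerance = 1e-6)
})

test_that("CUE profile objective is the continuous-updating GMM criterion", {
  for (seed in 1:5) {
    td <- random_trial(n = 50, k = 2, seed = seed)
    theta <- c(0.1, 0.4, -0.2, 0.3) + seed / 10
    expect_equal(as.numeric(gel_objective(theta, td, "CUE", k = 2)),
                 cu_gmm_criterion(theta, td, k = 2), tolerance = 1e-10)
  }
})

test_that("just-identified GEL equals the sample group means exactly", {
  td <- random_trial(n = 80, k = 1, seed = 6)
  y1 <- mean(td$y[td$z == 1L]); y0 <- mean(td$y[td$z == 0L])
  for (fam in c("EL", "ET", "CUE")) {
    fit <- gel_estimate(td, fam, k = 0)
    expect_equal(unname(fit$theta_hat), c(y1, y0 - y1), tolerance = 1e-10)
    expect_equal(fit$objective, 0)
    expect_true(fit$converged)
  }
})

test_that("implied probabilities normalize, stay positive (EL/ET), balance", {
  td <- simulate_trial(scenario(dist = "lognormal", rho = 0.5, delta = 0.2,
                                v1 = 2, beta2 = 0.5), seed = 31)
  for (fam in c("EL", "ET", "CUE")) {
    fit <- gel_estimate(td, fam, k = 2)
    expect_true(fit$converged)
    expect_equal(sum(fit$weights), 1, tolerance = 1e-12)
    if (fam != "CUE") expect_true(all(fit$weights > 0))
    # weighted moment conditions = covariate balance at the solution
    g <- moment_matrix(fit$theta_hat, td, k = 2)
    expect_lt(max(abs(colSums(fit$weights * g))), 1e-6)
    # weighted covariate means agree across groups
    for (j in 1:2) {
      w1 <- sum(fit$weights[td$z == 1] * td$X[td$z == 1, j]) /
        sum(fit$weights[td$z == 1])
      w0 <- sum(fit$weights[td$z == 0] * td$X[td$z == 0, j]) /
        sum(fit$weights[td$z == 0])
      expect_equal(w1, w0, tolerance = 1e-5)
    }
  }
})

test_that("a non-binding balance restriction leaves the estimate unadjusted", {
  # covariate with identical group means and no correlation with y
  set.seed(40)
  x <- rnorm(50)
  x <- c(x - mean(x), x - mean(x))  # same empirical distribution per group
  y <- rnorm(100)
  td <- trial_data(y, rep(c(0L, 1L), each = 50), matrix(x, ncol = 1))
  unadj <- mean(y[1:50]) - mean(y[51:100])
  for (fam in c("EL", "ET", "CUE")) {
    fit <- gel_estimate(td, fam, k = 1)
    expect_equal(fit$delta_hat, unadj, tolerance = 5e-3)
  }
})

test_that("estimates are invariant to observation order", {
  td <- simulate_trial(scenario(rho = 0.5), seed = 12)
  set.seed(1)
  perm <- sample(td$n)
  tdp <- trial_data(td$y[perm], td$z[perm], td$X[perm, , drop = FALSE])
  for (fam in c("EL", "ET", "CUE")) {
    f1 <- gel_estimate(td, fam, k = 2)
    f2 <- gel_estimate(tdp, fam, k = 2)
    expect_equal(f1$theta_hat, f2$theta_hat, tolerance = 1e-7)
  }
})

test_that("the three families agree to first order on normal data", {
  streams <- rng_substreams(55, 60)
  sc <- scenario(dist = "normal", rho = 0.5)
  agree <- vapply(streams, function(s) {
    td <- simulate_trial(sc, stream = s)
    d <- vapply(c("EL", "ET", "CUE"),
                function(f) gel_estimate(td, f, k = 1)$delta_hat, 0)
    max(dist(d))
  }, 0)
  expect_gt(mean(agree < 0.01), 0.95)
})

test_that("covariate balance buys efficiency at high correlation", {
  sc <- scenario(dist = "normal", rho = 0.9)
  streams <- rng_substreams(77, 300)
  ests <- t(vapply(streams, function(s) {
    td <- simulate_trial(sc, stream = s)
    c(gel = gel_estimate(td, "CUE", k = 2)$delta_hat,
      unadj = mean(td$y[td$z == 0]) - mean(td$y[td$z == 1]))
  }, c(0, 0)))
  expect_lt(var(ests[, "gel"]), var(ests[, "unadj"]))
  # the gain is large at rho = 0.9 (RMSE ratio ~ sqrt(1 - rho^2))
  expect_lt(sd(ests[, "gel"]) / sd(ests[, "unadj"]), 0.7)
})
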