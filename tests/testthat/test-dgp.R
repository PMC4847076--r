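test_that("equicorrelation matrix has the right structure and spectrum", {
  expect_equal(equicorrelation_matrix(3, 0), diag(3))
  m <- equicorrelation_matrix(3, 0.5)
  expect_true(all(m[upper.tri(m)] == 0.5))
  expect_equal(diag(m), rep(1, 3))
  # eigenvalues are 1 - rho (multiplicity dim-1) and 1 + (dim-1) rho
  expect_equal(sort(eigen(m, only.values = TRUE)$values),
               c(0.5, 0.5, 2), tolerance = 1e-12)
  m2 <- equicorrelation_matrix(2, 0.35)
  expect_equal(m2[1, 2], 0.35)
  expect_error(equicorrelation_matrix(3, -0.6), "positive definite")
  expect_error(equicorrelation_matrix(3, 1.0), "positive definite")
})

test_that("group assignment is the deterministic block layout", {
  z <- assign_groups(200, 0.5)
  expect_equal(z, rep(c(0L, 1L), each = 100))
  z2 <- assign_groups(200, 0.2)
  expect_equal(sum(z2 == 0L), 160L)
  expect_equal(sum(z2 == 1L), 40L)
  expect_true(all(diff(z2) >= 0))  # zeros strictly before ones
  expect_error(assign_groups(10, 0.25), "whole number")
})

test_that("base samples match the target first and second moments", {
  n_big <- 2e5
  for (d in c("normal", "t3", "lognormal")) {
    for (rho in c(0, 0.5)) {
      sc <- scenario(dist = d, rho = rho, n = n_big, k = 2)
      set.seed(42)
      b <- sample_base(sc)
      m <- cbind(b$y0, b$X)
      # mean 0 within ~4 SE (t3 variance is 1 so SE ~ 1/sqrt(n))
      expect_lt(max(abs(colMeans(m))), 4 / sqrt(n_big))
      # variance 1; t3 has infinite kurtosis, so give it a wide band
      tol_var <- if (d == "t3") 0.2 else 0.02
      expect_lt(max(abs(apply(m, 2, var) - 1)), tol_var)
      tol_cor <- if (d == "t3") 0.1 else 0.015
      cors <- cor(m)[upper.tri(diag(3))]
      expect_lt(max(abs(cors - rho)), tol_cor)
    }
  }
})

test_that("treatment transform only rescales and shifts the right group", {
  sc <- scenario(dist = "normal", rho = 0.5, n = 50, k = 2)
  set.seed(3)
  b <- sample_base(sc)
  z <- assign_groups(50, 0.5)
  expect_identical(apply_treatment_transform(b$y0, b$X, z, 1, 0, 0), b$y0)
  y <- apply_treatment_transform(b$y0, b$X, z, 2, 0.5, 0)
  expect_identical(y[z == 0L], b$y0[z == 0L])  # control untouched bit-for-bit
  expect_equal(y[z == 1L],
               sqrt(2) * b$y0[z == 1L] + 0.5 * rowSums(b$X[z == 1L, ]))
  yd <- apply_treatment_transform(b$y0, b$X, z, 1, 0, 0.7)
  expect_equal(yd[z == 0L], b$y0[z == 0L] + 0.7)
})

test_that("closed-form group-2 moments reproduce the five printed cases", {
  # Case parameters {delta, v1, beta2} with rho = 0.5, k = 2
  c1 <- theoretical_group2_moments(0.5, 2, 2, 0.5)
  expect_equal(round(c1$variance, 2), 4.16)
  expect_equal(round(c1$correlation, 2), 0.71)
  c2 <- theoretical_group2_moments(0.5, 2, 1, 0.5)
  expect_equal(round(c2$variance, 2), 2.75)
  expect_equal(round(c2$correlation, 2), 0.75)
  for (v1 in c(1, 2)) {  # no-interaction cases: variance v1, correlation rho
    cc <- theoretical_group2_moments(0.5, 2, v1, 0)
    expect_equal(cc$variance, v1)
    expect_equal(cc$correlation, 0.5 * sqrt(v1) / sqrt(v1))
  }
  # null transform leaves the base moments
  c0 <- theoretical_group2_moments(0.3, 2, 1, 0)
  expect_equal(c0$variance, 1)
  expect_equal(c0$correlation, 0.3)
})

test_that("Monte-Carlo group-2 moments match the closed form", {
  cases <- data.frame(v1 = c(2, 1, 1, 2, 2), beta2 = c(0.5, 0.5, 0, 0, 0))
  for (i in seq_len(nrow(cases))) {
    sc <- scenario(dist = "normal", rho = 0.5, delta = 0.5,
                   v1 = cases$v1[i], beta2 = cases$beta2[i],
                   n = 2e5, k = 2)
    td <- simulate_trial(sc, seed = 10 + i)
    th <- theoretical_group2_moments(0.5, 2, cases$v1[i], cases$beta2[i])
    y1 <- td$y[td$z == 1L]
    x1 <- td$X[td$z == 1L, 1L]
    expect_equal(var(y1), th$variance, tolerance = 0.03)
    expect_equal(cor(y1, x1), th$correlation, tolerance = 0.03)
  }
})

test_that("summary-statistic design has the stated moments and effect scale", {
  td <- sample_part3(0)  # uses current RNG; moments checked at large n below
  expect_equal(td$n, 200L)
  expect_equal(td$k, 1L)
  set.seed(5)
  big <- sample_part3(0.8, n_per_group = 5e4)
  y0 <- big$y[big$z == 0L]; y1 <- big$y[big$z == 1L]
  expect_equal(mean(y1), 1.82, tolerance = 0.02)
  expect_equal(mean(y0) - mean(y1), 0.8 * 0.58, tolerance = 0.02)
  expect_equal(mean(big$X), 1.07, tolerance = 0.02)
  expect_equal(sd(y1), 0.58, tolerance = 0.02)
  expect_equal(sd(big$X[, 1]), 0.52, tolerance = 0.02)
  # within a group (the pooled correlation is attenuated by the mean shift)
  expect_equal(cor(y1, big$X[big$z == 1L, 1]), 0.35, tolerance = 0.03)
  sc <- scenario_part3(0.5)
  expect_equal(sc$delta_true, 0.58 * 0.5)
})

test_that("the generator is a pure function of scenario and seed", {
  sc <- scenario(dist = "lognormal", rho = 0.3, delta = 0.2, v1 = 2,
                 beta2 = 0.5, n = 200, k = 2)
  a <- simulate_trial(sc, seed = 99)
  b <- simulate_trial(sc, seed = 99)
  expect_identical(a, b)
  streams <- rng_substreams(7, 3)
  s1 <- simulate_trial(sc, stream = streams[[2]])
  s2 <- simulate_trial(sc, stream = streams[[2]])
  expect_identical(s1, s2)
  expect_false(identical(simulate_trial(sc, stream = streams[[1]])$y, s1$y))
})

test_that("scenario validation rejects impossible parameterizations", {
  expect_error(scenario(rho = 1), "positive-definite")
  expect_error(scenario(rho = 0.5, delta = 0.25, n = 10), "whole number")
  expect_error(scenario(dist = "lognormal", rho = -0.2), "rho >= 0")
  expect_error(trial_data(c(1, 2), c(0, 2)), "only 0")
  expect_error(trial_data(c(1, NA), c(0, 1)), "missing")
  expect_error(trial_data(c(1, 2), c(1, 1)), "both groups")
})

test_that("scenario and trial data round-trip through their file formats", {
  sc <- scenario(dist = "t3", rho = 0.7, delta = 0.2, v1 = 2, beta2 = 0.5,
                 n = 100, k = 1)
  for (ext in c("yaml", "json")) {
    path <- file.path(tempdir(), paste0("sc.", ext))
    write_scenario(sc, path)
    expect_equal(read_scenario(path), sc)
  }
  td <- simulate_trial(sc, seed = 2)
  csv <- file.path(tempdir(), "trial.csv")
  write_trial_csv(td, csv)
  back <- read_trial_csv(csv)
  expect_equal(back$y, td$y)
  expect_equal(back$z, td$z)
  expect_equal(unname(back$X), unname(td$X))
})
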