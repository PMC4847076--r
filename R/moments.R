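#' Moment model for the two-group mean difference with covariate balance
#'
#' The estimand layout is `theta = (mu1, Delta, mux_1, ..., mux_k)` where
#' `mu1` is the intervention-group (`z = 1`) outcome mean, `Delta` the mean
#' difference control minus intervention (`E[y|z=0] - E[y|z=1]`), and `mux`
#' the common covariate means. There are `q = 2 + 2k` moment conditions for
#' `p = 2 + k` parameters: per-group outcome centering plus, for each
#' covariate, a balance condition in each group sharing the common mean. The
#' `k` overidentifying restrictions are exactly the covariate-balance
#' statements that deliver the efficiency gain of adjustment.
#'
#' @param k Number of adjustment covariates (0, 1 or 2 in the study; any
#'   `k >= 0` is accepted).
#' @return A list with `k`, `q`, `p`.
#' @export
moment_model <- function(k) {
  stopifnot(k >= 0, k == round(k))
  k <- as.integer(k)
  list(k = k, q = 2L + 2L * k, p = 2L + k)
}

#' Per-observation moment matrix
#'
#' Row `i` of the returned matrix is
#' \deqn{[\, z_i (y_i - \mu_1),\; (1 - z_i)(y_i - \mu_1 - \Delta),\;
#'   z_i (x_{i1} - \mu_{x1}),\; (1 - z_i)(x_{i1} - \mu_{x1}),\; \ldots \,]}
#' so each column has expectation zero at the true parameters under
#' randomization. With `k = 0` only the first two columns are present and the
#' model is just-identified.
#'
#' @param theta Parameter vector `(mu1, Delta, mux_1, ..., mux_k)`.
#' @param data A [trial_data] object.
#' @param k Number of covariates to use for adjustment (defaults to all
#'   columns of `data$X`).
#' @return An `n x (2 + 2k)` numeric matrix.
#' @export
moment_matrix <- function(theta, data, k = data$k) {
  stopifnot(inherits(data, "trial_data"), k >= 0, k <= data$k)
  k <- as.integer(k)
  if (length(theta) != 2L + k)
    stop("theta must have length ", 2L + k, " for k = ", k, call. = FALSE)
  z <- data$z
  y <- data$y
  g <- matrix(0, data$n, 2L + 2L * k)
  g[, 1L] <- z * (y - theta[1L])
  g[, 2L] <- (1 - z) * (y - theta[1L] - theta[2L])
  for (j in seq_len(k)) {
    xc <- data$X[, j] - theta[2L + j]
    g[, 2L * j + 1L] <- z * xc
    g[, 2L * j + 2L] <- (1 - z) * xc
  }
  g
}

#' Jacobian of the mean moment vector
#'
#' Analytic derivative of the column means of [moment_matrix] with respect to
#' `theta`. The moments are linear in `theta`, so the Jacobian is constant:
#' entries are minus the group frequencies in the pattern implied by the
#' moment layout.
#'
#' @inheritParams moment_matrix
#' @return A `q x p` matrix with `q = 2 + 2k`, `p = 2 + k`.
#' @export
moment_jacobian <- function(theta, data, k = data$k) {
  stopifnot(inherits(data, "trial_data"), k >= 0, k <= data$k)
  k <- as.integer(k)
  f1 <- mean(data$z)        # intervention fraction
  f0 <- 1 - f1
  G <- matrix(0, 2L + 2L * k, 2L + k)
  G[1L, 1L] <- -f1
  G[2L, 1L] <- -f0
  G[2L, 2L] <- -f0
  for (j in seq_len(k)) {
    G[2L * j + 1L, 2L + j] <- -f1
    G[2L * j + 2L, 2L + j] <- -f0
  }
  G
}

# Closed-form just-identified initializer: group means and covariate grand
# means. Solves the first two moment conditions exactly; for k >= 1 the
# covariate conditions cannot in general all be zeroed at uniform weights.
theta_init <- function(data, k) {
  y1 <- mean(data$y[data$z == 1L])
  y0 <- mean(data$y[data$z == 0L])
  c(y1, y0 - y1, if (k > 0L) colMeans(data$X[, seq_len(k), drop = FALSE]))
}
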