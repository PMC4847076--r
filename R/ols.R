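#' ANOVA/ANCOVA fit with classical and HC3 robust confidence intervals
#'
#' Ordinary least squares of the outcome on an intercept, the group indicator
#' and the first `k` covariates. The adjusted mean difference (control minus
#' intervention) is minus the coefficient on `z`. With `k = 0` the fit
#' reduces to ANOVA, i.e. the pooled-variance two-sample t procedure.
#' Confidence intervals use `t` quantiles with `n - p` degrees of freedom for
#' both the classical and the HC3 heteroscedasticity-consistent standard
#' errors. No treatment-by-covariate interaction terms are included: under an
#' interaction data-generating process this deliberate misspecification is
#' part of what the comparator is evaluated on.
#'
#' @param data A [trial_data].
#' @param k Number of covariates used for adjustment.
#' @param level Nominal confidence level (default 0.95).
#' @return An object of class `"ols_fit"`: list with `delta_hat`,
#'   `se_classical`, `se_hc3`, `ci_classical`, `ci_hc3`, `beta_x`, `coef`,
#'   `vcov_classical`, `vcov_hc3`, `residuals`, `leverages`, `df_residual`,
#'   `sigma2`, `xbar`, `n`, `k`, `level`.
#' @examples
#' td <- simulate_trial(scenario(rho = 0.5), seed = 7)
#' fit_ancova(td, k = 1)
#' @export
fit_ancova <- function(data, k = data$k, level = 0.95) {
  stopifnot(inherits(data, "trial_data"), k >= 0, k <= data$k,
            level > 0, level < 1)
  k <- as.integer(k)
  n <- data$n
  Xd <- cbind("(Intercept)" = 1, z = data$z,
              if (k > 0L) data$X[, seq_len(k), drop = FALSE])
  p <- ncol(Xd)
  qrx <- qr(Xd)
  if (qrx$rank < p) stop("design matrix is rank deficient", call. = FALSE)
  coef <- qr.coef(qrx, data$y)
  e <- data$y - drop(Xd %*% coef)
  xtx_inv <- chol2inv(qr.R(qrx))
  dimnames(xtx_inv) <- list(colnames(Xd), colnames(Xd))
  sigma2 <- sum(e^2) / (n - p)
  h <- rowSums((Xd %*% xtx_inv) * Xd)
  vc <- sigma2 * xtx_inv
  vr <- hc3_covariance(Xd, e, h)
  tq <- stats::qt(1 - (1 - level) / 2, df = n - p)
  delta_hat <- -coef[["z"]]
  se_c <- sqrt(vc["z", "z"])
  se_r <- sqrt(vr["z", "z"])
  out <- list(delta_hat = delta_hat,
              se_classical = se_c, se_hc3 = se_r,
              ci_classical = c(delta_hat - tq * se_c, delta_hat + tq * se_c),
              ci_hc3 = c(delta_hat - tq * se_r, delta_hat + tq * se_r),
              beta_x = if (k > 0L) coef[-(1:2)] else numeric(0),
              coef = coef, vcov_classical = vc, vcov_hc3 = vr,
              residuals = e, leverages = h, df_residual = n - p,
              sigma2 = sigma2,
              xbar = if (k > 0L) colMeans(data$X[, seq_len(k), drop = FALSE])
                     else numeric(0),
              n = n, k = k, level = level)
  class(out) <- "ols_fit"
  out
}

#' HC3 heteroscedasticity-consistent covariance matrix
#'
#' The sandwich estimator
#' `(X'X)^{-1} X' diag(e_i^2 / (1 - h_ii)^2) X (X'X)^{-1}`,
#' where `h_ii` are the hat-matrix leverages. The `(1 - h)^2` inflation makes
#' the estimator approximately unbiased under heteroscedasticity and finite
#' samples.
#'
#' @param design The `n x p` model matrix.
#' @param residuals OLS residuals.
#' @param leverages Hat-matrix diagonal (each strictly below 1); computed
#'   from `design` when omitted.
#' @return The `p x p` covariance matrix of the coefficient vector.
#' @export
hc3_covariance <- function(design, residuals, leverages = NULL) {
  design <- as.matrix(design)
  n <- nrow(design)
  stopifnot(length(residuals) == n)
  xtx_inv <- chol2inv(chol(crossprod(design)))
  if (is.null(leverages))
    leverages <- rowSums((design %*% xtx_inv) * design)
  if (any(leverages >= 1 - 1e-12))
    stop("leverage of 1: degenerate observation, HC3 undefined",
         call. = FALSE)
  u <- design * (residuals / (1 - leverages))
  v <- xtx_inv %*% crossprod(u) %*% xtx_inv
  dimnames(v) <- list(colnames(design), colnames(design))
  v
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("%s fit (k = %d, n = %d)\n",
              if (x$k == 0L) "ANOVA" else "ANCOVA", x$k, x$n))
  cat(sprintf("  mean difference (control - intervention): %.5f\n",
              x$delta_hat))
  cat(sprintf("  classical %.0f%% CI (%.5f; %.5f), se %.5f\n",
              100 * x$level, x$ci_classical[1L], x$ci_classical[2L],
              x$se_classical))
  cat(sprintf("  HC3       %.0f%% CI (%.5f; %.5f), se %.5f\n",
              100 * x$level, x$ci_hc3[1L], x$ci_hc3[2L], x$se_hc3))
  invisible(x)
}
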