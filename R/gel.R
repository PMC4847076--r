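#' GEL criterion ("distance") specifications
#'
#' Each member of the generalized empirical likelihood family is indexed by a
#' concave carrier function `rho(v)` normalized so that `rho(0) = 0`,
#' `rho'(0) = -1` and `rho''(0) = -1`:
#' \describe{
#'   \item{EL}{empirical likelihood, `rho(v) = log(1 - v)` on `v < 1`;}
#'   \item{ET}{exponential tilting, `rho(v) = 1 - exp(v)`;}
#'   \item{CUE}{continuous updating / Euclidean likelihood,
#'     `rho(v) = -v - v^2/2` (global domain).}
#' }
#' The choice of `rho` is the only difference between the three covariate
#' adjustment methods: it fixes the divergence between the uniform weights
#' `1/n` and the reweighting that enforces covariate balance.
#'
#' @param family One of `"EL"`, `"ET"`, `"CUE"` (case-insensitive).
#' @return A list with the family name and vectorized functions `rho`,
#'   `rho1`, `rho2` (value and first two derivatives).
#' @export
rho_spec <- function(family = c("EL", "ET", "CUE")) {
  family <- toupper(family)
  family <- match.arg(family)
  switch(family,
    EL = list(family = "EL",
              rho  = function(v) {
                out <- rep(-Inf, length(v))
                ok <- v < 1
                out[ok] <- log1p(-v[ok])
                out
              },
              rho1 = function(v) -1 / (1 - v),
              rho2 = function(v) -1 / (1 - v)^2),
    ET = list(family = "ET",
              rho  = function(v) 1 - exp(v),
              rho1 = function(v) -exp(v),
              rho2 = function(v) -exp(v)),
    CUE = list(family = "CUE",
               rho  = function(v) -v - v^2 / 2,
               rho1 = function(v) -1 - v,
               rho2 = function(v) rep(-1, length(v)))
  )
}

#' Inner Lagrange-multiplier maximization
#'
#' Maximizes the inner GEL criterion `P(lambda) = mean(rho(g %*% lambda))`
#' for a fixed moment matrix. For CUE the maximizer is available in closed
#' form, `lambda = -(g'g/n)^{-1} gbar`; for EL and ET a safeguarded Newton
#' iteration with backtracking is used. EL iterates are confined to the
#' domain `1 - lambda'g_i > 1/n` for every observation (Owen's safeguard), so
#' a single outlying moment cannot crash the solve — it fails gracefully with
#' `converged = FALSE` instead.
#'
#' @param g Numeric `n x q` moment matrix (e.g. from [moment_matrix]).
#' @param spec A [rho_spec] (or family name).
#' @param tol Convergence tolerance on the max-norm of the gradient.
#' @param max_iter Newton iteration cap.
#' @param lambda0 Optional warm start.
#' @return A list with `lambda`, `value` (the attained supremum of `P`),
#'   `converged`, `iterations`, `grad_norm`.
#' @export
solve_lambda <- function(g, spec, tol = 1e-10, max_iter = 100L,
                         lambda0 = NULL) {
  if (is.character(spec)) spec <- rho_spec(spec)
  g <- as.matrix(g)
  if (!all(is.finite(g))) stop("moment matrix must be finite", call. = FALSE)
  n <- nrow(g)
  q <- ncol(g)
  gbar <- colMeans(g)
  if (max(abs(gbar)) < 1e-13)
    return(list(lambda = numeric(q), value = 0, converged = TRUE,
                iterations = 0L, grad_norm = max(abs(gbar))))

  if (spec$family == "CUE") {
    omega <- crossprod(g) / n
    lambda <- tryCatch(-solve(omega, gbar), error = function(e)
      stop("rank-deficient second-moment matrix in CUE lambda solve",
           call. = FALSE))
    value <- drop(0.5 * crossprod(gbar, -lambda))  # = gbar' omega^{-1} gbar / 2
    return(list(lambda = lambda, value = value, converged = TRUE,
                iterations = 0L,
                grad_norm = max(abs(-gbar - omega %*% lambda))))
  }

  lambda <- if (is.null(lambda0)) numeric(q) else lambda0
  v <- drop(g %*% lambda)
  if (spec$family == "EL" && any(1 - v <= 1 / n)) {
    lambda <- numeric(q)
    v <- numeric(n)
  }
  obj <- mean(spec$rho(v))
  converged <- FALSE
  it <- 0L
  grad <- crossprod(g, spec$rho1(v)) / n
  while (it < max_iter) {
    if (max(abs(grad)) <= tol) { converged <- TRUE; break }
    it <- it + 1L
    H <- crossprod(g * spec$rho2(v), g) / n
    step <- tryCatch(-solve(H, grad), error = function(e) NULL)
    if (is.null(step)) step <- grad  # H singular: fall back to ascent
    step <- drop(step)
    t_ls <- 1
    ok <- FALSE
    for (bt in 1:60) {
      lam_new <- lambda + t_ls * step
      v_new <- drop(g %*% lam_new)
      domain_ok <- if (spec$family == "EL") all(1 - v_new > 1 / n) else TRUE
      if (domain_ok) {
        obj_new <- mean(spec$rho(v_new))
        if (is.finite(obj_new) && obj_new > obj - 1e-14) { ok <- TRUE; break }
      }
      t_ls <- t_ls / 2
    }
    if (!ok) break  # no admissible ascent step
    lambda <- lam_new
    v <- v_new
    obj <- obj_new
    grad <- crossprod(g, spec$rho1(v)) / n
  }
  list(lambda = drop(lambda), value = obj, converged = converged,
       iterations = it, grad_norm = max(abs(grad)))
}

#' Profile GEL objective at a parameter value
#'
#' The saddle objective `sup_lambda mean(rho(lambda' g_i(theta)))`, normalized
#' so it equals 0 when the mean moment vector is exactly zero (as in the
#' just-identified case at the sample means). For CUE it equals the
#' continuous-updating GMM criterion
#' `0.5 * gbar' [g'g/n]^{-1} gbar`.
#'
#' @inheritParams moment_matrix
#' @param family GEL family name (`"EL"`, `"ET"`, `"CUE"`).
#' @param tol Inner solver tolerance.
#' @return The objective value, with attributes `lambda` and `converged`.
#' @export
gel_objective <- function(theta, data, family = "CUE", k = data$k,
                          tol = 1e-10) {
  g <- moment_matrix(theta, data, k = k)
  sol <- solve_lambda(g, rho_spec(family), tol = tol)
  structure(sol$value, lambda = sol$lambda, converged = sol$converged)
}

# Envelope-theorem gradient of the profile objective with respect to theta.
# v = g lambda, r = rho'(v); the moments are linear in theta with
# observation-level derivative pattern given by the group indicator.
profile_gradient <- function(lambda, v, spec, data, k) {
  r <- spec$rho1(v)
  z <- data$z
  a <- r * z           # contributions through the z = 1 conditions
  b <- r * (1 - z)
  n <- data$n
  gr <- numeric(2L + k)
  gr[1L] <- -(sum(a) * lambda[1L] + sum(b) * lambda[2L]) / n
  gr[2L] <- -sum(b) * lambda[2L] / n
  for (j in seq_len(k)) {
    gr[2L + j] <- -(sum(a) * lambda[2L * j + 1L] +
                    sum(b) * lambda[2L * j + 2L]) / n
  }
  gr
}

#' Saddle-point GEL estimation of the adjusted mean difference
#'
#' Minimizes the profile GEL objective over
#' `theta = (mu1, Delta, mux_1..mux_k)`, optionally with `Delta` held fixed
#' (the restricted fit used by test inversion). The outer minimization runs
#' BFGS with the analytic envelope gradient, starting from the closed-form
#' just-identified initializer (group means and covariate grand means), with
#' a Nelder-Mead restart if BFGS fails to converge. With `k = 0` and no
#' restriction the model is just-identified and the estimate equals the
#' sample group means exactly.
#'
#' The implied probabilities are `w_i` proportional to
#' `-rho'(lambda' g_i)` normalized to sum to one; at the solution the
#' weighted moment conditions hold, so the weighted covariate means of the
#' two groups coincide (covariate balance). EL and ET weights are positive by
#' construction; CUE weights may be negative (Euclidean likelihood) — they
#' are reported, not clipped, and flagged in `negative_weights`.
#'
#' @param data A [trial_data].
#' @param family `"EL"`, `"ET"` or `"CUE"`.
#' @param k Number of covariates used for adjustment (defaults to all
#'   available).
#' @param fix_delta If non-`NULL`, hold the mean difference fixed at this
#'   value and profile out the remaining parameters.
#' @param fix Alternative to `fix_delta`: a single named value fixing any one
#'   parameter (`"mu1"`, `"delta"`, `"mux1"`, ...), e.g. `c(mu1 = 1.8)`.
#' @param init Optional starting value for the full parameter vector.
#' @param tol Convergence tolerance for the outer minimization.
#' @param inner_tol Tolerance for the inner multiplier solve.
#' @return An object of class `"gel_fit"`: list with `theta_hat` (named),
#'   `delta_hat`, `lambda_hat`, `objective`, `weights`, `converged`,
#'   `iterations`, `gradient_norm`, `negative_weights`, `family`, `k`, `n`.
#' @examples
#' td <- simulate_trial(scenario(rho = 0.5), seed = 42)
#' fit <- gel_estimate(td, family = "CUE", k = 2)
#' fit$delta_hat
#' @export
gel_estimate <- function(data, family = c("EL", "ET", "CUE"), k = data$k,
                         fix_delta = NULL, fix = NULL, init = NULL,
                         tol = 1e-9, inner_tol = 1e-11) {
  stopifnot(inherits(data, "trial_data"))
  family <- toupper(family[1L])
  spec <- rho_spec(family)
  k <- as.integer(k)
  stopifnot(k >= 0L, k <= data$k)
  q <- 2L + 2L * k
  p <- 2L + k
  pnames <- c("mu1", "delta", if (k > 0L) paste0("mux", seq_len(k)))

  if (!is.null(fix_delta)) fix <- c(delta = fix_delta)
  if (!is.null(fix)) {
    stopifnot(length(fix) == 1L, names(fix) %in% pnames)
    fix_idx <- match(names(fix), pnames)
  } else {
    fix_idx <- integer(0)
  }
  full0 <- if (is.null(init)) theta_init(data, k) else as.numeric(init)
  stopifnot(length(full0) == p)
  restricted <- length(fix_idx) > 0L
  free_idx <- setdiff(seq_len(p), fix_idx)

  assemble <- function(free) {
    th <- numeric(p)
    th[free_idx] <- free
    if (restricted) th[fix_idx] <- fix
    th
  }

  # Just-identified, unrestricted: closed form (method of moments).
  if (!restricted && q == p) {
    theta <- theta_init(data, k)
    names(theta) <- pnames
    g <- moment_matrix(theta, data, k = k)
    fit <- list(theta_hat = theta, delta_hat = theta[["delta"]],
                lambda_hat = numeric(q),
                objective = 0,
                weights = rep(1 / data$n, data$n),
                converged = TRUE, iterations = 0L,
                gradient_norm = max(abs(colMeans(g))),
                negative_weights = FALSE,
                family = family, k = k, n = data$n)
    class(fit) <- "gel_fit"
    return(fit)
  }

  lam_warm <- NULL
  bad_value <- 1e10
  fn <- function(free) {
    g <- moment_matrix(assemble(free), data, k = k)
    sol <- tryCatch(
      solve_lambda(g, spec, tol = inner_tol, lambda0 = lam_warm),
      error = function(e) NULL)
    if (is.null(sol) || !is.finite(sol$value)) return(bad_value)
    lam_warm <<- sol$lambda
    sol$value
  }
  gr <- function(free) {
    theta <- assemble(free)
    g <- moment_matrix(theta, data, k = k)
    sol <- tryCatch(
      solve_lambda(g, spec, tol = inner_tol, lambda0 = lam_warm),
      error = function(e) NULL)
    if (is.null(sol) || !is.finite(sol$value))
      return(numeric(length(free_idx)))
    lam_warm <<- sol$lambda
    v <- drop(g %*% sol$lambda)
    profile_gradient(sol$lambda, v, spec, data, k)[free_idx]
  }

  opt <- stats::optim(full0[free_idx], fn, gr, method = "BFGS",
                      control = list(reltol = tol, maxit = 300L))
  if (opt$convergence != 0L || opt$value >= bad_value) {
    opt2 <- stats::optim(full0[free_idx], fn, method = "Nelder-Mead",
                         control = list(reltol = tol, maxit = 2000L,
                                        warn.1d.NelderMead = FALSE))
    if (opt2$value < opt$value) opt <- opt2
  }

  theta <- assemble(opt$par)
  names(theta) <- pnames
  g <- moment_matrix(theta, data, k = k)
  sol <- tryCatch(solve_lambda(g, spec, tol = inner_tol, lambda0 = lam_warm),
                  error = function(e) NULL)
  if (is.null(sol)) {
    sol <- list(lambda = rep(NA_real_, q), value = NA_real_,
                converged = FALSE, iterations = 0L, grad_norm = NA_real_)
  }
  v <- if (all(is.finite(sol$lambda))) drop(g %*% sol$lambda) else
    rep(NA_real_, data$n)
  wraw <- -spec$rho1(v)
  weights <- wraw / sum(wraw)
  fit <- list(theta_hat = theta, delta_hat = theta[["delta"]],
              lambda_hat = sol$lambda,
              objective = sol$value,
              weights = weights,
              converged = isTRUE(sol$converged) && opt$convergence == 0L &&
                opt$value < bad_value,
              iterations = sol$iterations,
              gradient_norm = sol$grad_norm,
              negative_weights = isTRUE(any(weights < 0)),
              family = family, k = k, n = data$n)
  class(fit) <- "gel_fit"
  fit
}

#' @export
print.gel_fit <- function(x, ...) {
  cat(sprintf("%s covariate-adjusted fit (k = %d, n = %d)\n",
              x$family, x$k, x$n))
  print(round(x$theta_hat, 6))
  cat(sprintf("saddle objective %.3e, converged: %s\n",
              x$objective, x$converged))
  if (x$negative_weights)
    cat("note: some implied probabilities are negative (CUE)\n")
  invisible(x)
}
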