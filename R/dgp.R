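#' Equicorrelation matrix
#'
#' The common covariance structure of the simulated outcome and covariates:
#' unit variances and a single pairwise correlation `rho`. Its eigenvalues are
#' `1 - rho` (multiplicity `dim - 1`) and `1 + (dim - 1) * rho`, so positive
#' definiteness requires `rho` in `(-1/(dim-1), 1)`.
#'
#' @param dim Matrix dimension (>= 1).
#' @param rho Off-diagonal correlation.
#' @return A `dim x dim` positive-definite matrix.
#' @export
equicorrelation_matrix <- function(dim, rho) {
  stopifnot(length(dim) == 1L, dim >= 1, dim == round(dim),
            length(rho) == 1L, is.finite(rho))
  dim <- as.integer(dim)
  if (rho >= 1 || (dim > 1L && rho <= -1 / (dim - 1)))
    stop("equicorrelation matrix is not positive definite for rho = ", rho,
         " at dim = ", dim, call. = FALSE)
  m <- matrix(rho, dim, dim)
  diag(m) <- 1
  m
}

# Latent-Gaussian parameters for the centered multivariate lognormal with
# unit marginal variances and pairwise correlation rho:
#   marginal sigma^2 solves (e^{s} - 1) e^{s} = 1  =>  e^{s} = golden ratio,
#   cross-covariance c solves e^{s}(e^{c} - 1) = rho.
lognormal_latent <- function(rho, dim) {
  phi <- (1 + sqrt(5)) / 2
  s2 <- log(phi)
  cc <- log(1 + rho / phi)
  m <- matrix(cc, dim, dim)
  diag(m) <- s2
  list(sigma = m, mean_shift = sqrt(phi))
}

#' Draw the base (pre-treatment) outcome and covariates
#'
#' Draws `n` observations of the `(k + 1)`-variate vector `(y0, x1, ..., xk)`
#' from the scenario's distribution family, with each marginal having mean 0
#' and variance 1 and all pairwise correlations equal to `rho`:
#' \describe{
#'   \item{normal}{multivariate normal with the equicorrelation covariance;}
#'   \item{t3}{multivariate t with 3 df whose scale matrix is the
#'     equicorrelation matrix divided by 3, so marginal variances are 1;}
#'   \item{lognormal}{coordinate-wise exponential of a latent Gaussian whose
#'     covariance is solved so the lognormal has unit variances and
#'     correlations `rho`, then mean-centered.}
#' }
#' Uses the current RNG state; seed beforehand (or use [simulate_trial]).
#'
#' @param sc A [scenario].
#' @return A list with `y0` (length-`n` vector) and `X` (`n x k` matrix).
#' @export
sample_base <- function(sc) {
  stopifnot(inherits(sc, "scenario"))
  kdim <- sc$k + 1L
  n <- sc$n
  R <- equicorrelation_matrix(kdim, sc$rho)
  Z <- matrix(stats::rnorm(n * kdim), n, kdim)
  M <- switch(sc$dist,
    normal = Z %*% chol(R),
    t3 = {
      g <- Z %*% chol(R / 3)
      w <- stats::rchisq(n, df = 3) / 3
      g / sqrt(w)
    },
    lognormal = {
      lat <- lognormal_latent(sc$rho, kdim)
      exp(Z %*% chol(lat$sigma)) - lat$mean_shift
    })
  list(y0 = M[, 1L],
       X = M[, -1L, drop = FALSE])
}

#' Deterministic block group assignment
#'
#' Assigns the first `n * (1 - delta)` observations to the control group
#' (`z = 0`) and the remaining `n * delta` to the intervention group
#' (`z = 1`). Because the generated rows are exchangeable, this fixed layout
#' is equivalent in distribution to a random allocation.
#'
#' @param n Total sample size.
#' @param delta Fraction assigned to the intervention group.
#' @return Integer vector of 0s then 1s.
#' @export
assign_groups <- function(n, delta) {
  stopifnot(length(n) == 1L, n >= 2, n == round(n),
            length(delta) == 1L, delta > 0, delta < 1)
  n2 <- n * delta
  if (abs(n2 - round(n2)) > 1e-8)
    stop("n * delta = ", n2, " is not a whole number of observations",
         call. = FALSE)
  n2 <- as.integer(round(n2))
  rep(c(0L, 1L), times = c(as.integer(n) - n2, n2))
}

#' Apply the treatment transform to the base outcome
#'
#' Intervention-group outcomes (`z = 1`) are scaled by `sqrt(v1)` and then
#' shifted by `beta2 * (x_i1 + ... + x_ik)`, inducing heteroscedasticity
#' (`Var(y | z = 1) != 1`) and treatment-by-covariate interaction. Control
#' outcomes (`z = 0`) receive the true mean difference `delta_true` and are
#' otherwise untouched. The scaling uses the square root of `v1` so that
#' `v1` is itself the group-2 variance when `beta2 = 0` (see
#' [theoretical_group2_moments]).
#'
#' @param y0 Base outcome vector.
#' @param X Covariate matrix (may have zero columns).
#' @param z Group indicator.
#' @param v1 Group-2 variance parameter (> 0).
#' @param beta2 Interaction coefficient (>= 0).
#' @param delta_true True mean difference (control minus intervention).
#' @return The transformed outcome vector.
#' @export
apply_treatment_transform <- function(y0, X, z, v1, beta2, delta_true) {
  X <- as.matrix(X)
  n <- length(y0)
  stopifnot(length(z) == n, nrow(X) == n, v1 > 0, beta2 >= 0)
  interact <- if (ncol(X) > 0L) rowSums(X) else numeric(n)
  ifelse(z == 1L,
         sqrt(v1) * y0 + beta2 * interact,
         y0 + delta_true)
}

#' Theoretical group-2 moments after the treatment transform
#'
#' Closed-form variance of the transformed intervention-group outcome and its
#' correlation with each covariate, given the base equicorrelation `rho`, the
#' number of generated covariates `k`, and the transform parameters:
#' \deqn{Var(y | z=1) = v_1 + 2 \rho k \beta_2 \sqrt{v_1} +
#'   \beta_2^2 k (1 + (k-1)\rho)}
#' \deqn{Cor(y, x_j | z=1) = \frac{\rho \sqrt{v_1} + \beta_2 (1 + (k-1)\rho)}
#'   {\sqrt{Var(y | z=1)}}}
#'
#' @param rho Base pairwise correlation.
#' @param k Number of generated covariates (>= 1 for the correlation; with
#'   `k = 0` the variance is `v1` and the correlation is `NA`).
#' @param v1,beta2 Transform parameters.
#' @return A list with `variance` and `correlation`.
#' @examples
#' # Case 1 of the heteroscedasticity/interaction study:
#' theoretical_group2_moments(0.5, 2, 2, 0.5)  # variance 4.16, correlation 0.71
#' @export
theoretical_group2_moments <- function(rho, k, v1, beta2) {
  stopifnot(v1 > 0, k >= 0, k == round(k), beta2 >= 0)
  if (k == 0) return(list(variance = v1, correlation = NA_real_))
  v <- v1 + 2 * rho * k * beta2 * sqrt(v1) + beta2^2 * k * (1 + (k - 1) * rho)
  r <- (rho * sqrt(v1) + beta2 * (1 + (k - 1) * rho)) / sqrt(v)
  list(variance = v, correlation = r)
}

#' Simulate one trial from a scenario
#'
#' Draws the base variables, assigns groups deterministically, and applies
#' the treatment transform. The generator is a pure function of the scenario
#' and the RNG state: the same `seed` (or stream) gives bit-identical data.
#'
#' @param sc A [scenario] or [scenario_part3].
#' @param seed Optional integer seed (sets the L'Ecuyer-CMRG generator).
#' @param stream Optional full RNG state vector (a `.Random.seed`, e.g. one
#'   element of [rng_substreams]); takes precedence over `seed`.
#' @return A [trial_data] object.
#' @export
simulate_trial <- function(sc, seed = NULL, stream = NULL) {
  UseMethod("simulate_trial")
}

#' @export
simulate_trial.scenario <- function(sc, seed = NULL, stream = NULL) {
  set_rng(seed, stream)
  base <- sample_base(sc)
  z <- assign_groups(sc$n, sc$delta)
  y <- apply_treatment_transform(base$y0, base$X, z, sc$v1, sc$beta2,
                                 sc$delta_true)
  trial_data(y, z, base$X)
}

#' Scenario for the summary-statistic-based power study
#'
#' Parameterizes the third simulation part: a bivariate normal `(y, x)` with
#' covariate mean 1.07 in both arms, outcome standard deviation 0.58,
#' covariate standard deviation 0.52, and correlation 0.35 — the summary
#' statistics of the dust-control trial's log blood-lead concentrations —
#' with `n_per_group` observations per arm. The intervention-group outcome
#' mean is 1.82; the control-group mean is shifted upward by `delta_sd`
#' outcome standard deviations, i.e. by `0.58 * delta_sd` on the outcome
#' scale, so the power grid is expressed in standardized units.
#'
#' @param delta_sd True standardized mean difference (control minus
#'   intervention, in outcome-SD units), >= 0.
#' @param n_per_group Observations per arm (default 100).
#' @return An object of classes `"scenario_part3"` and `"scenario"`. Its
#'   `delta_true` element holds the truth on the outcome scale
#'   (`0.58 * delta_sd`), which is what coverage and RMSE are measured
#'   against.
#' @export
scenario_part3 <- function(delta_sd = 0, n_per_group = 100L) {
  stopifnot(delta_sd >= 0, n_per_group >= 2)
  structure(
    list(dist = "normal", rho = 0.35, delta = 0.5, v1 = 1, beta2 = 0,
         n = 2L * as.integer(n_per_group), k = 1L,
         delta_sd = delta_sd, delta_true = 0.58 * delta_sd,
         mu_y = 1.82, mu_x = 1.07, sd_y = 0.58, sd_x = 0.52),
    class = c("scenario_part3", "scenario")
  )
}

#' @export
simulate_trial.scenario_part3 <- function(sc, seed = NULL, stream = NULL) {
  set_rng(seed, stream)
  sample_part3(sc$delta_sd, n_per_group = sc$n %/% 2L)
}

#' Draw one trial from the summary-statistic-based design
#'
#' See [scenario_part3] for the design. Uses the current RNG state.
#'
#' @param delta_sd True standardized mean difference; the control-group
#'   outcome mean is `1.82 + 0.58 * delta_sd`.
#' @param n_per_group Observations per arm.
#' @return A [trial_data] with one covariate.
#' @export
sample_part3 <- function(delta_sd, n_per_group = 100L) {
  stopifnot(delta_sd >= 0)
  n <- 2L * as.integer(n_per_group)
  Sigma <- matrix(c(0.58^2, 0.35 * 0.58 * 0.52,
                    0.35 * 0.58 * 0.52, 0.52^2), 2L, 2L)
  M <- matrix(stats::rnorm(n * 2L), n, 2L) %*% chol(Sigma)
  z <- assign_groups(n, 0.5)
  y <- M[, 1L] + 1.82 + 0.58 * delta_sd * (1L - z)
  x <- M[, 2L] + 1.07
  trial_data(y, z, matrix(x, ncol = 1L, dimnames = list(NULL, "x1")))
}

#' Reproducible per-replicate RNG substreams
#'
#' Spawns `n` independent L'Ecuyer-CMRG substreams from a root seed, so that
#' replicate `r` of a simulation is reproducible in isolation and under any
#' parallel schedule.
#'
#' @param seed Root integer seed.
#' @param n Number of substreams.
#' @return A list of `n` RNG state vectors usable as `stream` arguments.
#' @export
rng_substreams <- function(seed, n) {
  stopifnot(length(seed) == 1L, is.finite(seed), n >= 1)
  old_kind <- RNGkind()
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    RNGkind(old_kind[1L], old_kind[2L], old_kind[3L])
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  suppressWarnings(RNGkind("L'Ecuyer-CMRG"))
  set.seed(as.integer(seed))
  s <- get(".Random.seed", globalenv())
  out <- vector("list", n)
  for (i in seq_len(n)) {
    s <- parallel::nextRNGStream(s)
    out[[i]] <- s
  }
  out
}

# Set the RNG from either an integer seed (L'Ecuyer-CMRG) or a full state
# vector; leaves the RNG untouched when both are NULL.
set_rng <- function(seed = NULL, stream = NULL) {
  if (!is.null(stream)) {
    assign(".Random.seed", stream, globalenv())
  } else if (!is.null(seed)) {
    suppressWarnings(set.seed(as.integer(seed), kind = "L'Ecuyer-CMRG"))
  }
  invisible(NULL)
}
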