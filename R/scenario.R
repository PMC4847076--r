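#' Define a simulation scenario
#'
#' A scenario fully parameterizes the data-generating process for one
#' simulated two-arm trial: the joint distribution family of the outcome and
#' covariates, their common pairwise correlation, the group-size split, the
#' group-2 variance multiplier, the treatment-by-covariate interaction
#' coefficient, and the true mean difference.
#'
#' @param dist Distribution family of `(y, x1, ..., xk)`: `"normal"`,
#'   `"t3"` (multivariate t with 3 df, rescaled to unit marginal variance), or
#'   `"lognormal"` (exponentiated Gaussian, mean-centered, with the latent
#'   covariance solved so marginal variances are 1 and correlations `rho`).
#' @param rho Common pairwise correlation of outcome and covariates, in
#'   `[0, 1)`.
#' @param delta Fraction of the `n` observations assigned to group 2
#'   (`z = 1`); `n * delta` must be a whole number.
#' @param v1 Variance parameter for group 2: the group-2 outcome is scaled by
#'   `sqrt(v1)` so that `Var(y | z = 1) = v1` when `beta2 = 0`.
#' @param beta2 Treatment-by-covariate interaction coefficient:
#'   `beta2 * (x1 + ... + xk)` is added to the group-2 outcome.
#' @param n Total sample size.
#' @param k Number of covariates generated (0, 1 or 2).
#' @param delta_true True mean difference, group 1 (control, `z = 0`) minus
#'   group 2 (intervention, `z = 1`); added to the control outcomes.
#'
#' @return An object of class `"scenario"` (a validated list of the above).
#' @examples
#' sc <- scenario(dist = "normal", rho = 0.5, n = 200)
#' td <- simulate_trial(sc, seed = 1)
#' @export
scenario <- function(dist = c("normal", "t3", "lognormal"), rho = 0.5,
                     delta = 0.5, v1 = 1, beta2 = 0, n = 200, k = 2,
                     delta_true = 0) {
  dist <- match.arg(dist)
  stopifnot(is.numeric(rho), length(rho) == 1L, is.finite(rho))
  stopifnot(is.numeric(n), length(n) == 1L, n >= 4, n == round(n))
  stopifnot(is.numeric(k), length(k) == 1L, k %in% 0:2)
  stopifnot(is.numeric(v1), length(v1) == 1L, v1 > 0)
  stopifnot(is.numeric(beta2), length(beta2) == 1L, beta2 >= 0)
  stopifnot(is.numeric(delta_true), length(delta_true) == 1L,
            is.finite(delta_true))
  if (delta <= 0 || delta >= 1)
    stop("'delta' must be in (0, 1)", call. = FALSE)
  n2 <- n * delta
  if (abs(n2 - round(n2)) > 1e-8)
    stop("n * delta must be a whole number of observations", call. = FALSE)
  kdim <- k + 1L
  if (rho >= 1 || (kdim > 1L && rho <= -1 / (kdim - 1)) || (kdim == 1L && rho < 0))
    stop("'rho' does not give a positive-definite equicorrelation matrix",
         call. = FALSE)
  if (dist == "lognormal" && rho < 0)
    stop("the centered-lognormal construction requires rho >= 0", call. = FALSE)
  structure(
    list(dist = dist, rho = rho, delta = delta, v1 = v1, beta2 = beta2,
         n = as.integer(n), k = as.integer(k), delta_true = delta_true),
    class = "scenario"
  )
}

#' @export
print.scenario <- function(x, ...) {
  cat("Trial simulation scenario\n")
  cat(sprintf("  distribution: %s, rho = %g, k = %d covariates\n",
              x$dist, x$rho, x$k))
  cat(sprintf("  n = %d (%d control / %d intervention)\n",
              x$n, as.integer(x$n * (1 - x$delta)), as.integer(x$n * x$delta)))
  cat(sprintf("  v1 = %g, beta2 = %g, true difference = %g\n",
              x$v1, x$beta2, x$delta_true))
  invisible(x)
}

#' Construct a trial data set
#'
#' Bundles an outcome vector, a binary group indicator and an optional
#' covariate matrix into the container every estimator in the package
#' consumes, after validating it.
#'
#' @param y Numeric outcome vector of length `n`.
#' @param z Group indicator vector in `{0, 1}`; both groups must be present.
#' @param X Numeric `n x k` covariate matrix (or `NULL` / zero columns for an
#'   unadjusted analysis).
#' @return An object of class `"trial_data"`: a list with elements `y`, `z`,
#'   `X` (always a matrix, possibly with zero columns) and `n`, `k`.
#' @export
trial_data <- function(y, z, X = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(numeric(0), nrow = n, ncol = 0L)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) != n) stop("X must have one row per observation", call. = FALSE)
  if (length(z) != n) stop("y and z must have equal length", call. = FALSE)
  if (anyNA(y) || anyNA(z) || anyNA(X))
    stop("trial data must not contain missing values", call. = FALSE)
  if (!all(z %in% c(0, 1)))
    stop("z must contain only 0 (control) and 1 (intervention)", call. = FALSE)
  z <- as.integer(z)
  if (sum(z) == 0L || sum(z) == n)
    stop("both groups must be present in z", call. = FALSE)
  if (!all(is.finite(y)) || (ncol(X) > 0L && !all(is.finite(X))))
    stop("trial data must be finite", call. = FALSE)
  if (ncol(X) > 0L && is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  structure(list(y = y, z = z, X = X, n = n, k = ncol(X)),
            class = "trial_data")
}

#' @export
print.trial_data <- function(x, ...) {
  cat(sprintf("Trial data: n = %d (%d control, %d intervention), %d covariate(s)\n",
              x$n, sum(x$z == 0L), sum(x$z == 1L), x$k))
  invisible(x)
}

#' Read and write trial data as CSV
#'
#' The on-disk format is a plain CSV with header columns `y`, `z`,
#' `x1, ..., xk`, with `z` coded 0/1.
#'
#' @param path File path.
#' @param data A [trial_data] object (for writing).
#' @return `read_trial_csv` returns a [trial_data] object;
#'   `write_trial_csv` invisibly returns `path`.
#' @export
read_trial_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("y", "z") %in% names(df)))
    stop("CSV must contain columns 'y' and 'z'", call. = FALSE)
  xcols <- grep("^x[0-9]+$", names(df), value = TRUE)
  xcols <- xcols[order(as.integer(sub("^x", "", xcols)))]
  X <- if (length(xcols)) as.matrix(df[xcols]) else NULL
  trial_data(df$y, df$z, X)
}

#' @rdname read_trial_csv
#' @export
write_trial_csv <- function(data, path) {
  stopifnot(inherits(data, "trial_data"))
  df <- data.frame(y = data$y, z = data$z)
  if (data$k > 0L) df <- cbind(df, as.data.frame(data$X))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read and write scenario configurations
#'
#' Scenarios serialize to YAML or JSON; the format is chosen from the file
#' extension (`.yml`/`.yaml` vs `.json`).
#'
#' @param x A [scenario] object (for writing).
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_scenario` returns a [scenario]; `write_scenario` invisibly
#'   returns `path`.
#' @export
read_scenario <- function(path) {
  lst <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(scenario, lst[intersect(names(lst), names(formals(scenario)))])
}

#' @rdname read_scenario
#' @export
write_scenario <- function(x, path) {
  stopifnot(inherits(x, "scenario"))
  lst <- unclass(x)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(lst, path)
  }
  invisible(path)
}
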