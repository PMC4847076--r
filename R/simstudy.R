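METHOD_KEYS <- c("el", "et", "cue", "ancova", "ancova_hc3")

# Canonical display label for a method at a given adjustment k.
method_label <- function(key, k) {
  switch(key,
         el = "EL", et = "ET", cue = "CUE",
         ancova = if (k == 0L) "ANOVA" else "ANCOVA",
         ancova_hc3 = if (k == 0L) "ANOVA_HC3" else "ANCOVA_HC3",
         stop("unknown method: ", key, call. = FALSE))
}

#' Run one simulation replicate
#'
#' Draws a single trial from the scenario and fits every requested method
#' with `k` adjustment covariates, returning one row per method. The result
#' is deterministic given the RNG stream (or seed).
#'
#' For the GEL methods two inference modes are available. `"lr"` (default)
#' evaluates the profiled LR statistic at the scenario's true difference and
#' at 0 and records the coverage/rejection indicators through the exact
#' test-inversion duality (a value is inside the 95% CI iff its statistic is
#' below the chi-squared(1) critical value); the CI bounds are then `NA`.
#' `"invert"` computes the full test-inversion interval via [invert_ci].
#'
#' @param sc A [scenario] or [scenario_part3].
#' @param methods Character vector among `"el"`, `"et"`, `"cue"`,
#'   `"ancova"`, `"ancova_hc3"` (`"ancova"` is labelled ANOVA when `k = 0`).
#' @param k Number of covariates used for adjustment.
#' @param seed,stream RNG control, as in [simulate_trial].
#' @param level Nominal confidence level.
#' @param gel_inference `"lr"` or `"invert"` (see Details).
#' @param replicate_id Identifier copied into the output.
#' @return A data.frame with columns `replicate_id`, `method`, `estimate`,
#'   `ci_lower`, `ci_upper`, `covered`, `rejected`, `converged`.
#' @export
run_replicate <- function(sc, methods = "ancova", k = 0L, seed = NULL,
                          stream = NULL, level = 0.95,
                          gel_inference = c("lr", "invert"),
                          replicate_id = 1L) {
  gel_inference <- match.arg(gel_inference)
  methods <- match.arg(tolower(methods), METHOD_KEYS, several.ok = TRUE)
  data <- simulate_trial(sc, seed = seed, stream = stream)
  k <- as.integer(k)
  stopifnot(k <= data$k)
  crit <- stats::qchisq(level, df = 1)
  dtrue <- sc$delta_true

  ols <- if (any(methods %in% c("ancova", "ancova_hc3")))
    fit_ancova(data, k = k, level = level)

  rows <- lapply(methods, function(m) {
    if (m %in% c("ancova", "ancova_hc3")) {
      ci <- if (m == "ancova") ols$ci_classical else ols$ci_hc3
      data.frame(replicate_id = replicate_id,
                 method = method_label(m, k),
                 estimate = ols$delta_hat,
                 ci_lower = ci[1L], ci_upper = ci[2L],
                 covered = ci[1L] <= dtrue && dtrue <= ci[2L],
                 rejected = 0 < ci[1L] || 0 > ci[2L],
                 converged = TRUE)
    } else {
      fit <- gel_estimate(data, family = toupper(m), k = k)
      if (gel_inference == "invert") {
        ci <- invert_ci(data, family = toupper(m), k = k, level = level,
                        fit = fit)
        data.frame(replicate_id = replicate_id,
                   method = method_label(m, k),
                   estimate = fit$delta_hat,
                   ci_lower = ci$lower, ci_upper = ci$upper,
                   covered = isTRUE(ci$lower <= dtrue && dtrue <= ci$upper),
                   rejected = isTRUE(0 < ci$lower || 0 > ci$upper),
                   converged = fit$converged && ci$converged)
      } else {
        d_true <- lr_statistic(dtrue, data, family = toupper(m), k = k,
                               fit = fit)
        d_null <- if (dtrue == 0) d_true else
          lr_statistic(0, data, family = toupper(m), k = k, fit = fit)
        data.frame(replicate_id = replicate_id,
                   method = method_label(m, k),
                   estimate = fit$delta_hat,
                   ci_lower = NA_real_, ci_upper = NA_real_,
                   covered = as.numeric(d_true) <= crit,
                   rejected = as.numeric(d_null) > crit,
                   converged = fit$converged &&
                     isTRUE(attr(d_true, "converged")) &&
                     isTRUE(attr(d_null, "converged")))
      }
    }
  })
  do.call(rbind, rows)
}

#' Run a Monte-Carlo simulation for one scenario
#'
#' Repeats [run_replicate] over independent per-replicate RNG substreams
#' spawned from the root seed, so the output is identical across runs and
#' any parallel schedule honoring the substream rule.
#'
#' @inheritParams run_replicate
#' @param reps Number of replicates.
#' @param seed Root seed.
#' @param progress Emit a progress message to stderr every `progress`
#'   replicates (0 = silent).
#' @return A data.frame of stacked [run_replicate] rows.
#' @export
run_simulation <- function(sc, methods = "ancova", k = 0L, reps = 1000L,
                           seed = 1L, level = 0.95,
                           gel_inference = c("lr", "invert"),
                           progress = 0L) {
  gel_inference <- match.arg(gel_inference)
  streams <- rng_substreams(seed, reps)
  out <- vector("list", reps)
  for (r in seq_len(reps)) {
    out[[r]] <- run_replicate(sc, methods = methods, k = k,
                              stream = streams[[r]], level = level,
                              gel_inference = gel_inference,
                              replicate_id = r)
    if (progress > 0L && r %% progress == 0L)
      message(sprintf("  replicate %d/%d", r, reps))
  }
  do.call(rbind, out)
}

#' Aggregate replicate results into RMSE, coverage and rejection rate
#'
#' Non-convergent replicates are excluded per method, with the convergent
#' count reported, so a failed fit never contaminates the aggregates.
#'
#' @param results Output of [run_simulation] (or stacked [run_replicate]s).
#' @param delta_true True mean difference used for the RMSE (coverage and
#'   rejection indicators were fixed at simulation time).
#' @return A data.frame with one row per method: `method`,
#'   `n_reps_requested`, `n_converged`, `rmse`, `coverage`,
#'   `rejection_rate`.
#' @export
aggregate_results <- function(results, delta_true = 0) {
  stopifnot(is.data.frame(results), nrow(results) > 0L)
  split_res <- split(results, results$method)
  rows <- lapply(names(split_res), function(m) {
    rs <- split_res[[m]]
    ok <- rs[rs$converged, , drop = FALSE]
    if (nrow(ok) == 0L)
      stop("no converged replicates for method ", m, call. = FALSE)
    data.frame(method = m,
               n_reps_requested = nrow(rs),
               n_converged = nrow(ok),
               rmse = sqrt(mean((ok$estimate - delta_true)^2)),
               coverage = mean(ok$covered),
               rejection_rate = mean(ok$rejected))
  })
  do.call(rbind, rows)
}

# Scenario grids behind the published table layouts.
part2_cases <- function() {
  data.frame(case = 1:5,
             delta = c(0.2, 0.5, 0.2, 0.5, 0.2),
             v1    = c(2,   1,   1,   2,   2),
             beta2 = c(0.5, 0.5, 0,   0,   0))
}

#' Reproduce one of the published simulation tables
#'
#' Re-runs the Monte-Carlo study behind a given results table and returns (or
#' writes) a long-format data.frame with the same scenario rows and the
#' aggregate columns `rmse`, `coverage`, `rejection_rate`, `n_converged`.
#' Tables 1-3: homoscedastic equal-group scenarios with 0, 1, 2 adjustment
#' covariates across the correlation grid. Tables 4-6: the five
#' heteroscedasticity/interaction cases. Table 7: HC3-robust ANCOVA coverage
#' for the five cases and 0-2 covariates. Table 8: size and power across the
#' standardized-difference grid of the summary-statistic design.
#'
#' OLS-family methods default to 10,000 replicates; the GEL methods default
#' to 1,000 (the test-inversion path is the expensive one — a note is logged;
#' set `reps` to override both).
#'
#' @param table_id Integer 1-8.
#' @param reps Replicates for every method (overrides the per-method
#'   defaults).
#' @param seed Root seed.
#' @param methods Methods to include (default: the ones in the cited table).
#' @param dists,rhos,cases,delta_grid Optional subsets of the table's
#'   scenario grid, to run a slice cheaply.
#' @param out Optional CSV path to write.
#' @param progress Log per-scenario progress to stderr.
#' @return A data.frame (invisibly also written to `out` when given).
#' @export
reproduce_table <- function(table_id, reps = NULL, seed = 1L, methods = NULL,
                            dists = NULL, rhos = NULL, cases = NULL,
                            delta_grid = NULL, out = NULL, progress = TRUE) {
  stopifnot(length(table_id) == 1L, table_id %in% 1:8)
  ols_reps <- if (is.null(reps)) 10000L else as.integer(reps)
  gel_reps <- if (is.null(reps)) 1000L else as.integer(reps)
  if (is.null(reps))
    message("GEL methods run at ", gel_reps,
            " replicates by default (test inversion is the expensive path); ",
            "pass 'reps' to override")
  note <- function(...) if (isTRUE(progress)) message(...)

  run_cell <- function(sc, k, meths, scen_cols) {
    rows <- lapply(meths, function(m) {
      r <- if (m %in% c("ancova", "ancova_hc3")) ols_reps else gel_reps
      res <- run_simulation(sc, methods = m, k = k, reps = r, seed = seed)
      agg <- aggregate_results(res, delta_true = sc$delta_true)
      nc <- agg$n_reps_requested - agg$n_converged
      if (nc > 0) note(sprintf("  %s: %d non-convergent replicate(s) excluded",
                               agg$method, nc))
      cbind(scen_cols, agg, row.names = NULL)
    })
    do.call(rbind, rows)
  }

  all_dists <- c("normal", "t3", "lognormal")
  if (is.null(dists)) dists <- all_dists
  grid_rows <- list()

  if (table_id %in% 1:3) {
    k <- table_id - 1L
    if (is.null(rhos)) rhos <- if (table_id == 1L) 0.5 else
      c(0, 0.1, 0.3, 0.5, 0.7, 0.9)
    if (is.null(methods)) methods <- c("el", "et", "cue", "ancova")
    for (rho in rhos) for (d in dists) {
      note(sprintf("table %d: dist=%s rho=%g", table_id, d, rho))
      sc <- scenario(dist = d, rho = rho, k = 2L)
      grid_rows[[length(grid_rows) + 1L]] <-
        run_cell(sc, k, methods,
                 data.frame(table = table_id, dist = d, rho = rho, k = k))
    }
  } else if (table_id %in% 4:6) {
    k <- table_id - 4L
    cs <- part2_cases()
    if (is.null(cases)) cases <- cs$case
    if (is.null(methods)) methods <- c("el", "et", "cue", "ancova")
    for (cid in cases) for (d in dists) {
      note(sprintf("table %d: case %d dist=%s", table_id, cid, d))
      pr <- cs[cs$case == cid, ]
      sc <- scenario(dist = d, rho = 0.5, delta = pr$delta, v1 = pr$v1,
                     beta2 = pr$beta2, k = 2L)
      grid_rows[[length(grid_rows) + 1L]] <-
        run_cell(sc, k, methods,
                 data.frame(table = table_id, case = cid, dist = d, k = k))
    }
  } else if (table_id == 7L) {
    cs <- part2_cases()
    if (is.null(cases)) cases <- cs$case
    if (is.null(methods)) methods <- "ancova_hc3"
    for (cid in cases) for (k in 0:2) for (d in dists) {
      note(sprintf("table 7: case %d k=%d dist=%s", cid, k, d))
      pr <- cs[cs$case == cid, ]
      sc <- scenario(dist = d, rho = 0.5, delta = pr$delta, v1 = pr$v1,
                     beta2 = pr$beta2, k = 2L)
      grid_rows[[length(grid_rows) + 1L]] <-
        run_cell(sc, k, methods,
                 data.frame(table = 7L, case = cid, dist = d, k = k))
    }
  } else {
    if (is.null(delta_grid)) delta_grid <- seq(0, 0.8, by = 0.1)
    if (is.null(methods)) methods <- c("el", "et", "cue", "ancova")
    for (dl in delta_grid) {
      note(sprintf("table 8: Delta=%g", dl))
      sc <- scenario_part3(delta_sd = dl)
      grid_rows[[length(grid_rows) + 1L]] <-
        run_cell(sc, 1L, methods,
                 data.frame(table = 8L, delta_true = dl, k = 1L))
    }
  }

  res <- do.call(rbind, grid_rows)
  if (!is.null(out)) utils::write.csv(res, out, row.names = FALSE)
  invisible(res)
}

#' Analyze a trial data set with one adjustment method
#'
#' Fits the requested method to a CSV file (columns `y`, `z`, `x1..xk`) or a
#' [trial_data] object and reports point estimates with 95% confidence
#' intervals in the layout of a covariate-adjusted trial report: `mu1`
#' (intervention-group outcome mean), `delta` (mean difference, control minus
#' intervention) and, for the GEL methods, the common covariate means `mux`
#' with test-inversion CIs — or, for ANCOVA, the covariate slopes `beta_x`
#' with classical t CIs.
#'
#' @param input Path to a CSV file or a [trial_data].
#' @param method One of `"el"`, `"et"`, `"cue"`, `"ancova"`, `"ancova_hc3"`.
#' @param k Number of covariates to adjust for.
#' @param level Confidence level.
#' @param out Optional JSON path to write the report to.
#' @return A list (class `"trial_report"`) with one `estimate`/`lower`/
#'   `upper` entry per parameter.
#' @export
analyze_dataset <- function(input, method = "cue", k = NULL, level = 0.95,
                            out = NULL) {
  data <- if (inherits(input, "trial_data")) input else read_trial_csv(input)
  method <- match.arg(tolower(method), METHOD_KEYS)
  if (is.null(k)) k <- data$k
  k <- as.integer(k)
  stopifnot(k >= 0L, k <= data$k)

  entry <- function(est, lo, hi)
    list(estimate = unname(est), lower = unname(lo), upper = unname(hi))
  rep_list <- list(method = method_label(method, k), level = level, k = k,
                   n = data$n)

  if (method %in% c("ancova", "ancova_hc3")) {
    fit <- fit_ancova(data, k = k, level = level)
    vc <- if (method == "ancova") fit$vcov_classical else fit$vcov_hc3
    tq <- stats::qt(1 - (1 - level) / 2, df = fit$df_residual)
    # intervention-group adjusted mean: intercept + z + slopes at covariate
    # grand means
    cvec <- c(1, 1, fit$xbar)
    mu1 <- sum(cvec * fit$coef)
    se_mu1 <- sqrt(drop(t(cvec) %*% vc %*% cvec))
    se_d <- sqrt(vc["z", "z"])
    rep_list$mu1 <- entry(mu1, mu1 - tq * se_mu1, mu1 + tq * se_mu1)
    rep_list$delta <- entry(fit$delta_hat, fit$delta_hat - tq * se_d,
                            fit$delta_hat + tq * se_d)
    if (k > 0L) {
      rep_list$beta_x <- lapply(seq_len(k), function(j) {
        nm <- names(fit$beta_x)[j]
        se <- sqrt(vc[nm, nm])
        entry(fit$beta_x[j], fit$beta_x[j] - tq * se, fit$beta_x[j] + tq * se)
      })
      names(rep_list$beta_x) <- names(fit$beta_x)
    }
  } else {
    fit <- gel_estimate(data, family = toupper(method), k = k)
    for (pn in names(fit$theta_hat)) {
      ci <- invert_ci(data, family = toupper(method), k = k, level = level,
                      fit = fit, param = pn)
      el <- entry(fit$theta_hat[[pn]], ci$lower, ci$upper)
      if (pn == "mu1") rep_list$mu1 <- el
      else if (pn == "delta") rep_list$delta <- el
      else rep_list$mux <- c(rep_list$mux, stats::setNames(list(el), pn))
    }
    rep_list$converged <- fit$converged
  }
  class(rep_list) <- "trial_report"
  if (!is.null(out))
    jsonlite::write_json(unclass(rep_list), out, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  rep_list
}

#' @export
print.trial_report <- function(x, ...) {
  cat(sprintf("%s analysis (n = %d, k = %d, %.0f%% CIs)\n",
              x$method, x$n, x$k, 100 * x$level))
  show <- function(nm, e)
    cat(sprintf("  %-6s %8.5f  (%.5f; %.5f)\n", nm, e$estimate, e$lower,
                e$upper))
  show("mu1", x$mu1)
  show("delta", x$delta)
  for (nm in names(x$mux)) show(nm, x$mux[[nm]])
  for (nm in names(x$beta_x)) show(nm, x$beta_x[[nm]])
  invisible(x)
}
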