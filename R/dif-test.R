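#' Score-based test of measurement invariance (overall DIF test)
#'
#' End-to-end workflow: fit the IRT model, compute case-wise score
#' contributions, centre them, estimate the score covariance, build the
#' covariate-ordered cumulative score process, reduce it to a test statistic
#' and compute a p-value.  The null model states that all item parameters
#' are invariant across the covariate; with a `group` column, ability
#' differences between the groups (impact) are part of the null model and do
#' not trigger rejections.
#'
#' Engine and statistic defaults follow standard practice: the double-maximum
#' statistic for continuous covariates, the unordered LM statistic for
#' categorical ones; the `"asymptotic"` engine decorrelates with the pooled
#' covariance (closed-form Brownian-bridge / chi-square references), while
#' the `"simulation"` engine uses group-wise covariances when a group column
#' is present and compares against simulated paths constrained to the
#' observed end point.
#'
#' @inheritParams fit_irt
#' @param covariate Name of the column in `data` holding the DIF covariate
#'   (numeric for continuous ordering; factor/character for categories).
#' @param engine `"asymptotic"` (pooled variance) or `"simulation"`.
#' @param statistic `"auto"` (default: DM if the covariate is numeric,
#'   LM_uo otherwise), `"dm"`, or `"lmuo"`.
#' @param weighted Bin-width weighting of the LM statistic (default `TRUE`).
#' @param R Simulation replicates for the simulation engine.
#' @param seed Seed for the simulation engine.
#' @param fit An already fitted [fit_irt()] object for these data, to skip
#'   refitting.
#' @return A `dif_test` object carrying the fit, the score process and the
#'   `test_result`; see [tidy.dif_test()] and [glance.dif_test()].
#' @examples
#' dat <- sim_dataset(n_persons = 400, n_items = 5, model = "2PL",
#'                    covariate = "categorical", seed = 7)
#' dif_test(dat, covariate = "covariate", model = "2PL", method = "MML")
#' @export
dif_test <- function(data, covariate, items = NULL, group = NULL,
                     model = c("2PL", "3PL"), method = c("MML", "MAP"),
                     prior = NULL, engine = c("asymptotic", "simulation"),
                     statistic = c("auto", "dm", "lmuo"), weighted = TRUE,
                     R = 1000, seed = NULL, quad = quadrature(),
                     control = list(), fit = NULL) {
  engine <- match.arg(engine)
  statistic <- match.arg(statistic)
  model <- match.arg(model)
  method <- match.arg(method)
  if (!covariate %in% names(data)) {
    rlang::abort(paste0("covariate column '", covariate, "' not found"),
                 class = "scoredif_config_error")
  }
  cov_vals <- data[[covariate]]
  if (statistic == "auto") {
    statistic <- if (is.numeric(cov_vals)) "dm" else "lmuo"
  }
  if (statistic == "lmuo" && is.numeric(cov_vals) &&
      length(unique(cov_vals)) > 12) {
    rlang::abort("LM_uo needs a categorical covariate",
                 class = "scoredif_config_error")
  }
  fit <- fit %||% fit_irt(data, items = items, model = model, method = method,
                          prior = prior, group = group, quad = quad,
                          control = control)
  scores <- center_scores(score_contributions(fit))
  groups <- if (!is.null(group)) data[[group]]
  cov_mode <- if (engine == "simulation" && !is.null(group)) "groupwise" else "pooled"
  V <- score_covariance(scores, mode = cov_mode, groups = groups)
  proc <- build_process(scores, V, cov_vals, groups = groups)

  result <- if (engine == "asymptotic") {
    if (statistic == "dm") {
      stat <- dm_statistic(proc)
      test_result("dm", stat, pvalue_dm_asymptotic(stat, proc$k),
                  engine = "asymptotic", k = proc$k, N = proc$N)
    } else {
      bins <- categorical_bins(proc$covariate)
      stat <- lmuo_statistic(proc, bins, weighted = TRUE)
      test_result("lmuo", stat,
                  pvalue_lmuo_asymptotic(stat, proc$k, bins$m),
                  engine = "asymptotic", k = proc$k, N = proc$N, m = bins$m)
    }
  } else {
    pvalue_simulation(proc, statistic = statistic, R = R, seed = seed,
                      weighted = weighted)
  }
  structure(list(fit = fit, process = proc, result = result,
                 covariate = covariate, engine = engine),
            class = "dif_test")
}

#' @export
print.dif_test <- function(x, alpha = NULL, ...) {
  cat("Score-based measurement invariance test\n")
  cat("  model:", x$fit$model, "/", x$fit$method,
      if (!is.null(x$fit$prior)) "(with item priors)", "\n")
  cat("  covariate:", x$covariate, " N =", x$process$N,
      " k =", x$process$k, "\n  ")
  print(x$result)
  if (!is.null(alpha)) {
    cat(sprintf("  p %s %.3g at the chosen reporting level\n",
                if (x$result$p < alpha) "<" else ">=", alpha))
  }
  invisible(x)
}

#' Tidy and glance methods
#'
#' `tidy()` on a fitted model returns one row per item with the parameter
#' estimates; on a `dif_test` it returns the one-row test summary.
#' `glance()` returns one-row model-level summaries.
#'
#' @param x An `irt_fit` or `dif_test` object.
#' @param ... Unused.
#' @name scoredif-broom
NULL

#' @rdname scoredif-broom
#' @exportS3Method generics::tidy
tidy.irt_fit <- function(x, ...) {
  out <- tibble::as_tibble(x$params)
  if (x$model == "2PL") out$c <- NULL
  out
}

#' @rdname scoredif-broom
#' @exportS3Method generics::glance
glance.irt_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, method = x$method,
    n_persons = x$data$N, n_items = x$data$J,
    n_groups = nrow(x$group_params),
    logLik = x$loglik,
    logPost = x$logpost %||% NA_real_,
    em_iterations = x$convergence$em_iterations,
    gradient_sup_norm = x$convergence$gradient_sup_norm
  )
}

#' @rdname scoredif-broom
#' @exportS3Method generics::tidy
tidy.dif_test <- function(x, ...) {
  r <- x$result
  tibble::tibble(statistic = r$statistic, value = r$value, p.value = r$p,
                 engine = r$engine, R = r$R, k = r$k, N = r$N, m = r$m)
}

#' @rdname scoredif-broom
#' @exportS3Method generics::glance
glance.dif_test <- function(x, ...) {
  dplyr::bind_cols(tidy.dif_test(x),
                   glance.irt_fit(x$fit)[c("model", "method", "logLik")])
}

#' @exportS3Method generics::tidy
tidy.item_params <- function(x, ...) tibble::as_tibble(x)

#' @export
print.irt_fit <- function(x, ...) {
  cat(x$model, "model,", x$method, "estimation:",
      x$data$N, "persons,", x$data$J, "items,",
      nrow(x$group_params), "group(s)\n")
  cat("  logLik:", format(x$loglik, digits = 8),
      " (EM iterations:", x$convergence$em_iterations,
      ", gradient sup-norm:",
      format(x$convergence$gradient_sup_norm, digits = 3), ")\n")
  print(tidy.irt_fit(x))
  invisible(x)
}

#' Plot a fitted DIF test
#'
#' Shows the cumulative score process underlying the test, annotated with
#' the statistic and p-value.
#'
#' @param object A `dif_test`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.dif_test <- function(object, ...) {
  autoplot.score_process(object$process) +
    ggplot2::labs(subtitle = sprintf("%s = %.3f, p = %.4g (%s engine)",
                                     object$result$statistic,
                                     object$result$value, object$result$p,
                                     object$result$engine))
}
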