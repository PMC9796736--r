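# Test statistics on the cumulative score process and their p-value engines.

#' Double-maximum statistic
#'
#' \eqn{DM = \max_i \max_j |\Psi(i/N)_j|}: the largest absolute excursion of
#' the decorrelated cumulative score process over observations and parameter
#' components.  Suited to continuous ordering covariates; its pooled-route
#' reference distribution is the supremum of `k` independent standard
#' Brownian bridges.
#'
#' @param process A [build_process()] result.
#' @return Nonnegative scalar.
#' @export
dm_statistic <- function(process) {
  max(abs(process$psi))
}

#' Category bins of an ordered categorical covariate
#'
#' Boundaries \eqn{i_l = N t_l}, where \eqn{t_l} is the proportion of
#' respondents in the first `l` categories of the sorted covariate, with
#' \eqn{i_0 = 0} and \eqn{i_m = N}.
#'
#' @param covariate Factor or character vector in process (sorted) order.
#' @return A list with `boundaries` (length m+1), `t` (boundaries/N),
#'   `m`, and per-bin `counts`.
#' @export
categorical_bins <- function(covariate) {
  f <- if (is.factor(covariate)) covariate else factor(covariate)
  counts <- as.integer(table(f))
  if (any(counts == 0)) {
    rlang::abort("empty covariate category", class = "scoredif_config_error")
  }
  boundaries <- c(0L, cumsum(counts))
  list(boundaries = boundaries, t = boundaries / length(f),
       m = length(counts), counts = counts, levels = levels(f))
}

#' Unordered Lagrange multiplier statistic
#'
#' Sums squared process increments across covariate categories,
#' \eqn{LM_{uo} = \sum_{l=1}^{m} \sum_j \{\Psi(i_l/N)_j -
#' \Psi(i_{l-1}/N)_j\}^2 / (t_l - t_{l-1})} in the default weighted form,
#' whose pooled-route reference is chi-square with \eqn{k(m-1)} degrees of
#' freedom.  `weighted = FALSE` drops the bin-width weights; that form has no
#' closed-form reference and is intended for the simulation engine.
#'
#' @param process A [build_process()] result whose covariate is categorical.
#' @param bins Optional [categorical_bins()]; derived from the process
#'   covariate when missing.
#' @param weighted Use bin-width weights (default `TRUE`).
#' @return Nonnegative scalar.
#' @export
lmuo_statistic <- function(process, bins = NULL, weighted = TRUE) {
  bins <- bins %||% categorical_bins(process$covariate)
  vals <- process$psi[bins$boundaries + 1, , drop = FALSE]
  inc <- diff(vals)
  w <- if (weighted) diff(bins$t) else rep(1, bins$m)
  sum(rowSums(inc^2) / w)
}

#' Asymptotic p-value of the double-maximum statistic
#'
#' Uses the Kolmogorov-distribution tail for the supremum of one standard
#' Brownian bridge, \eqn{p_1(x) = 2\sum_{j\ge1} (-1)^{j+1} e^{-2j^2x^2}}
#' (series truncated when a term drops below 1e-12 or after 100 terms), and
#' component independence after decorrelation:
#' \eqn{p = 1 - (1 - p_1(x))^k}.
#'
#' @param stat Observed DM value (nonnegative).
#' @param k Number of item-parameter components.
#' @export
pvalue_dm_asymptotic <- function(stat, k) {
  stopifnot(stat >= 0, k >= 1)
  p1 <- if (stat == 0) 1 else {
    s <- 0
    for (j in 1:100) {
      term <- exp(-2 * j^2 * stat^2)
      s <- s + (-1)^(j + 1) * term
      if (term < 1e-12) break
    }
    min(1, max(0, 2 * s))
  }
  1 - (1 - p1)^k
}

#' Asymptotic p-value of the weighted unordered LM statistic
#'
#' Upper-tail chi-square probability with \eqn{k(m-1)} degrees of freedom.
#'
#' @param stat Observed weighted LM value.
#' @param k Number of item-parameter components.
#' @param m Number of covariate categories.
#' @export
pvalue_lmuo_asymptotic <- function(stat, k, m) {
  stopifnot(stat >= 0, k >= 1, m >= 2)
  stats::pchisq(stat, df = k * (m - 1), lower.tail = FALSE)
}

#' Simulation-based p-value
#'
#' Simulates the reference distribution of the test statistic under
#' invariance: each replicate draws `N` iid standard normal `k`-vectors
#' \eqn{s_i}, shifts them by \eqn{\tilde s_i = s_i - \bar s + \Psi(1)/\sqrt N}
#' so the simulated path \eqn{N^{-1/2}\sum_{i \le \lfloor Nt \rfloor}
#' \tilde s_i} shares the observed process's start and end point, and
#' computes the same statistic on the simulated path.  Standard normal draws
#' are already decorrelated, so no further groupwise transform applies.  The
#' p-value is the add-one estimator \eqn{(1 + \#\{T_{sim} \ge T_{obs}\}) /
#' (R + 1)}, never exactly zero.
#'
#' @param process The observed (decorrelated, covariate-ordered) process.
#' @param statistic `"dm"` or `"lmuo"`.
#' @param R Number of replicates (at least 99).
#' @param seed Integer seed; the same seed and inputs reproduce the p-value
#'   exactly.
#' @param bins [categorical_bins()] for `"lmuo"`; derived from the process
#'   covariate when missing.
#' @param weighted Bin-width weighting for `"lmuo"`.
#' @return A `test_result` list: statistic name, value, `p`, engine,
#'   `R`, `seed`, `k`, `N`, `m`.
#' @export
pvalue_simulation <- function(process, statistic = c("dm", "lmuo"), R = 1000,
                              seed = NULL, bins = NULL, weighted = TRUE) {
  statistic <- match.arg(statistic)
  if (R < 99) {
    rlang::abort("simulation engine needs R >= 99 replicates",
                 class = "scoredif_config_error")
  }
  N <- process$N; k <- process$k
  psi_end <- process$psi[N + 1, ]
  if (statistic == "lmuo") {
    bins <- bins %||% categorical_bins(process$covariate)
    t_obs <- lmuo_statistic(process, bins, weighted)
    binid <- rep(seq_len(bins$m), bins$counts)
    w <- if (weighted) diff(bins$t) else rep(1, bins$m)
  } else {
    t_obs <- dm_statistic(process)
  }
  sims <- with_preserved_seed(seed, {
    vapply(seq_len(R), function(r) {
      S <- matrix(stats::rnorm(N * k), N, k)
      shift <- psi_end / sqrt(N) - colMeans(S)
      if (statistic == "dm") {
        S <- S + matrix(shift, N, k, byrow = TRUE)
        path <- apply(S, 2, cumsum) / sqrt(N)
        max(abs(path))
      } else {
        inc <- (rowsum(S, binid) +
                  outer(bins$counts, shift)) / sqrt(N)
        sum(rowSums(inc^2) / w)
      }
    }, numeric(1))
  })
  p <- (1 + sum(sims >= t_obs)) / (R + 1)
  test_result(statistic = statistic, value = t_obs, p = p,
              engine = "simulation", R = R, seed = seed, k = k, N = N,
              m = if (statistic == "lmuo") bins$m else NA_integer_)
}

test_result <- function(statistic, value, p, engine, R = NA_integer_,
                        seed = NULL, k, N, m = NA_integer_) {
  structure(list(statistic = unname(c(dm = "DM", lmuo = "LM_uo")[statistic]),
                 value = value, p = p, engine = engine, R = R,
                 seed = seed, k = k, N = N, m = m),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s = %.4f, p = %.4g (%s engine%s)\n",
              x$statistic, x$value, x$p, x$engine,
              if (x$engine == "simulation") paste0(", R = ", x$R) else ""))
  invisible(x)
}
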