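# Case-wise score contributions and their decorrelated cumulative process.

# per-pattern score rows; returns item-parameter scores (patterns x k) and
# group-parameter scores (patterns x 2(G-1)), the latter only used for
# gradient diagnostics and never entering the test statistics
pattern_scores <- function(rd, params, group_params, quad, es = NULL) {
  es <- es %||% estep(rd, params, group_params, quad)
  P <- nrow(rd$Ypat); Q <- quad$n
  pars <- item_par_names(attr(params, "model") %||%
                           if (all(params$c == 0)) "2PL" else "3PL")
  model <- if (length(pars) == 2) "2PL" else "3PL"
  k <- length(pars) * rd$J
  S <- matrix(0, P, k)
  x <- quad$x
  for (j in seq_len(rd$J)) {
    Pj <- es$pt$P[j, ]; sj <- es$pt$s[j, ]; cj <- params$c[j]
    denom <- Pj * (1 - Pj)
    M <- (outer(rd$Ypat[, j], rep(1, Q)) -
            matrix(Pj, P, Q, byrow = TRUE)) /
      matrix(denom, P, Q, byrow = TRUE)
    W <- es$post * M
    ss <- (1 - cj) * sj * (1 - sj)
    prof <- cbind(x * ss, ss, if (model == "3PL") 1 - sj)
    cols <- (j - 1) * length(pars) + seq_along(pars)
    S[, cols] <- W %*% prof
  }
  colnames(S) <- as.vector(t(outer(params$item, pars, paste, sep = "_")))

  ng <- nrow(group_params)
  Sg <- NULL
  if (ng > 1) {
    Sg <- matrix(0, P, 2 * (ng - 1))
    colnames(Sg) <- as.vector(t(outer(paste0("group", 2:ng),
                                      c("mean", "var"), paste, sep = "_")))
    for (gi in 2:ng) {
      mu <- group_params$mean[gi]; v <- group_params$var[gi]
      w <- exp(group_log_weights(quad, mu, v))
      u <- (x - mu) / v
      vv <- ((x - mu)^2 - v) / (2 * v^2)
      idx <- rd$gpat == gi
      post_g <- es$post[idx, , drop = FALSE]
      Sg[idx, 2 * (gi - 2) + 1] <- post_g %*% u - sum(w * u)
      Sg[idx, 2 * (gi - 2) + 2] <- post_g %*% vv - sum(w * vv)
    }
  }
  list(item = S, group = Sg)
}

#' Case-wise score contributions at the fitted parameters
#'
#' Row `i` is the gradient of person `i`'s log marginal likelihood with
#' respect to the stacked item-parameter vector (item-major order:
#' `a_1, d_1[, c_1], a_2, ...`), evaluated at the estimates via the posterior
#' quadrature weights.  The raw rows sum (over persons) to approximately zero
#' at an MML optimum and to minus the log-prior gradient at a MAP optimum.
#'
#' Scores of the group (impact) parameters are computed as well and attached
#' as attribute `"group_scores"` for gradient diagnostics; they are excluded
#' from covariance estimation, decorrelation and the test statistics, which
#' use item-parameter information only.
#'
#' @param fit An [fit_irt()] object.
#' @return An `N x k` matrix of class `score_matrix` with attribute
#'   `state = "raw"`.
#' @export
score_contributions <- function(fit) {
  sc <- pattern_scores(fit$data, fit$params, fit$group_params, fit$quad)
  S <- sc$item[fit$data$id, , drop = FALSE]
  if (!all(is.finite(S))) {
    bad <- unique(which(!is.finite(S), arr.ind = TRUE)[, 2])
    rlang::abort(paste0("non-finite score contributions in column(s) ",
                        paste(colnames(S)[bad], collapse = ", ")),
                 class = "scoredif_numeric_error")
  }
  structure(S, state = "raw",
            group_scores = if (!is.null(sc$group)) sc$group[fit$data$id, , drop = FALSE],
            class = c("score_matrix", "matrix", "array"))
}

score_state <- function(scores) attr(scores, "state") %||% "raw"

#' Centre a score matrix
#'
#' Subtracts the column means so every column sums to zero.  Centring is
#' harmless under MML (means are already near zero) and required under MAP,
#' where the raw score sum equals minus the log-prior gradient.
#'
#' @param scores A `score_matrix`.
#' @return The centred `score_matrix` (`state = "centered"`); idempotent.
#' @export
center_scores <- function(scores) {
  S <- sweep(unclass(scores), 2, colMeans(scores))
  structure(S, state = "centered",
            class = c("score_matrix", "matrix", "array"))
}

#' Score covariance estimate
#'
#' Pooled mode computes \eqn{\hat V = N^{-1} \sum_i \tilde\psi_i
#' \tilde\psi_i^\top}; groupwise mode computes
#' \eqn{\hat V_g = N_g^{-1}\sum_{i \in g} \tilde\psi_i \tilde\psi_i^\top}
#' per group, where centring always used the global mean (the null model
#' asserts a common expectation; group-specific centring would absorb DIF
#' signal).  The divisor is the group (or total) size, not size minus one,
#' matching the asymptotic estimator.
#'
#' @param scores A centred `score_matrix`.
#' @param mode `"pooled"` or `"groupwise"`.
#' @param groups Group labels (length N), required for `"groupwise"`.
#' @return A `score_covariance` object caching the inverse square roots.
#' @export
score_covariance <- function(scores, mode = c("pooled", "groupwise"),
                             groups = NULL) {
  mode <- match.arg(mode)
  if (score_state(scores) != "centered") {
    rlang::abort("scores must be centred before covariance estimation",
                 class = "scoredif_state_error")
  }
  S <- unclass(scores)
  if (mode == "pooled") {
    V <- crossprod(S) / nrow(S)
    out <- list(mode = mode, V = V, inv_sqrt = matrix_inv_sqrt(V))
  } else {
    if (is.null(groups)) {
      rlang::abort("groupwise covariance requires group labels",
                   class = "scoredif_config_error")
    }
    gl <- sort(unique(groups))
    Vg <- lapply(gl, function(g) {
      Sg <- S[groups == g, , drop = FALSE]
      crossprod(Sg) / nrow(Sg)
    })
    names(Vg) <- as.character(gl)
    out <- list(mode = mode, V = Vg,
                inv_sqrt = lapply(Vg, matrix_inv_sqrt), levels = gl)
  }
  structure(out, class = "score_covariance")
}

#' Symmetric inverse square root
#'
#' Returns the symmetric matrix `S` with `S %*% V %*% S = I`, via the
#' eigendecomposition of `V`; eigenvalues below the singularity tolerance
#' raise an error naming the most involved parameter column.
#'
#' @param V Symmetric positive-definite matrix.
#' @param tol Eigenvalue singularity tolerance.
#' @export
matrix_inv_sqrt <- function(V, tol = 1e-10) {
  e <- eigen((V + t(V)) / 2, symmetric = TRUE)
  if (any(e$values < tol)) {
    j <- which.max(abs(e$vectors[, which.min(e$values)]))
    lab <- colnames(V)[j] %||% paste0("column ", j)
    rlang::abort(paste0("singular score covariance (near-degenerate direction ",
                        "dominated by ", lab, ")"),
                 class = "scoredif_singular")
  }
  out <- e$vectors %*% (t(e$vectors) / sqrt(e$values))
  dimnames(out) <- dimnames(V)
  (out + t(out)) / 2
}

#' Build the covariate-ordered cumulative score process
#'
#' Persons are sorted by the covariate (stable sort; ties keep original row
#' order; factor covariates sort by level order), each centred score row is
#' decorrelated with the pooled \eqn{\hat V^{-1/2}} or its own group's
#' \eqn{\hat V_{g(i)}^{-1/2}}, and the scaled partial sums
#' \eqn{\Psi(i/N) = N^{-1/2} \sum_{i' \le i} \hat V_{g(i')}^{-1/2}
#' \tilde\psi_{i'}} are accumulated, with \eqn{\Psi(0) = 0}.  Pooled
#' decorrelation makes the path end at 0 at \eqn{t = 1}; groupwise
#' decorrelation generally does not in finite multiple-group samples.
#'
#' @param scores A centred `score_matrix`.
#' @param cov A [score_covariance()] estimate.
#' @param covariate Numeric or factor, length N: the DIF covariate that
#'   orders the persons.
#' @param groups Group labels (length N) for groupwise decorrelation;
#'   must match the labels used in `cov`.
#' @return A `score_process` object.
#' @export
build_process <- function(scores, cov, covariate, groups = NULL) {
  if (score_state(scores) != "centered") {
    rlang::abort("scores must be centred before building the process",
                 class = "scoredif_state_error")
  }
  S <- unclass(scores)
  N <- nrow(S)
  if (length(covariate) != N) {
    rlang::abort("covariate length does not match the score matrix",
                 class = "scoredif_config_error")
  }
  if (cov$mode == "pooled") {
    G <- S %*% cov$inv_sqrt
  } else {
    if (is.null(groups)) {
      rlang::abort("groupwise decorrelation requires group labels",
                   class = "scoredif_config_error")
    }
    G <- S
    for (g in cov$levels) {
      idx <- groups == g
      G[idx, ] <- S[idx, , drop = FALSE] %*% cov$inv_sqrt[[as.character(g)]]
    }
  }
  ord <- order(covariate, method = "radix")   # stable: original index tie-break
  G <- G[ord, , drop = FALSE]
  psi <- rbind(0, apply(G, 2, cumsum) / sqrt(N))
  colnames(psi) <- colnames(S)
  structure(list(
    psi = psi, t = seq(0, N) / N,
    covariate = covariate[ord],
    group = if (!is.null(groups)) groups[ord],
    mode = cov$mode, k = ncol(S), N = N
  ), class = "score_process")
}

#' @export
print.score_process <- function(x, ...) {
  cat("Cumulative score process: N =", x$N, ", k =", x$k,
      ", decorrelation =", x$mode, "\n")
  cat("  end point sup-norm |Psi(1)| =",
      format(max(abs(x$psi[x$N + 1, ])), digits = 4), "\n")
  invisible(x)
}

#' Tidy a cumulative score process
#'
#' @param x A `score_process`.
#' @param ... Unused.
#' @return A tibble with columns `t`, `component`, `value` and (if group
#'   labels were supplied) `group`, suitable for export or plotting.
#' @exportS3Method generics::tidy
tidy.score_process <- function(x, ...) {
  out <- tibble::tibble(
    t = rep(x$t, x$k),
    component = rep(colnames(x$psi) %||% paste0("par", seq_len(x$k)),
                    each = x$N + 1),
    value = as.vector(x$psi)
  )
  if (!is.null(x$group)) {
    out$group <- rep(c(NA, as.character(x$group)), x$k)
  }
  out
}

#' Fluctuation plot of a cumulative score process
#'
#' One line per parameter component of \eqn{\Psi(t)} against the ordering
#' fraction `t`; under measurement invariance the paths fluctuate randomly
#' around zero, while DIF related to the ordering covariate shows up as
#' systematic excursions.
#'
#' @param object A `score_process`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.score_process <- function(object, ...) {
  df <- tidy.score_process(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value,
                                   group = .data$component)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "ordering fraction t",
                  y = expression(Psi(t)),
                  title = "Cumulative score process") +
    ggplot2::theme_minimal()
}
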