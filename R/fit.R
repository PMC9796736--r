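#' Ability quadrature grid
#'
#' The latent ability distribution is integrated over a fixed grid of
#' equally spaced nodes; node weights are normal densities at the group's
#' `(mean, var)`, renormalised to sum to one.  The default (61 nodes on
#' \[-6, 6\]) matches the convention of the common IRT software family.
#'
#' @param n Number of nodes.
#' @param range Length-2 numeric, grid end points.
#' @export
quadrature <- function(n = 61, range = c(-6, 6)) {
  structure(list(x = seq(range[1], range[2], length.out = n), n = n),
            class = "quadrature")
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

row_logsumexp <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

# normalized log quadrature weights for a N(mean, var) ability distribution
group_log_weights <- function(quad, mean, var) {
  lw <- stats::dnorm(quad$x, mean, sqrt(var), log = TRUE)
  lw - logsumexp(lw)
}

# ---- internal data representation -----------------------------------------

# Collapse a response matrix to unique (group, pattern) rows with counts.
prep_responses <- function(Y, g) {
  storage.mode(Y) <- "double"
  if (anyNA(Y)) {
    rlang::abort("missing responses are not supported",
                 class = "scoredif_data_error")
  }
  if (!all(Y %in% c(0, 1))) {
    rlang::abort("responses must be binary 0/1", class = "scoredif_data_error")
  }
  cm <- colMeans(Y)
  if (any(cm == 0 | cm == 1)) {
    bad <- colnames(Y)[cm == 0 | cm == 1]
    rlang::abort(paste0("degenerate item(s) with constant responses: ",
                        paste(bad, collapse = ", ")),
                 class = "scoredif_data_error")
  }
  key <- paste(g, apply(Y, 1, paste, collapse = ""))
  first <- !duplicated(key)
  id <- match(key, key[first])
  list(
    Y = Y, g = g, N = nrow(Y), J = ncol(Y), items = colnames(Y),
    Ypat = Y[first, , drop = FALSE], gpat = g[first],
    counts = as.numeric(tabulate(id, sum(first))), id = id
  )
}

# P (items x nodes) response probabilities, plus pieces reused by gradients
prob_table <- function(params, quad) {
  a <- params$a; d <- params$d; c <- params$c
  s <- stats::plogis(outer(a, quad$x) + d)       # J x Q logistic part
  P <- c + (1 - c) * s
  P <- pmin(pmax(P, 1e-12), 1 - 1e-12)
  list(P = P, s = s)
}

# pattern x node log-likelihood and posterior weights
estep <- function(rd, params, group_params, quad) {
  pt <- prob_table(params, quad)
  logL <- rd$Ypat %*% log(pt$P) + (1 - rd$Ypat) %*% log1p(-pt$P)  # Pp x Q
  lw <- t(vapply(seq_len(nrow(group_params)), function(g) {
    group_log_weights(quad, group_params$mean[g], group_params$var[g])
  }, numeric(quad$n)))                                             # G x Q
  logpost <- logL + lw[rd$gpat, , drop = FALSE]
  llpat <- row_logsumexp(logpost)
  post <- exp(logpost - llpat)
  list(post = post, llpat = llpat, loglik = sum(rd$counts * llpat),
       pt = pt, lw = lw)
}

# ---- M-step ---------------------------------------------------------------

item_box <- function(model) {
  if (model == "2PL") {
    list(lower = c(1e-4, -50), upper = c(50, 50))
  } else {
    list(lower = c(1e-4, -50, 1e-4), upper = c(50, 50, 1 - 1e-4))
  }
}

# expected-count binomial objective for one item over the quadrature nodes
mstep_item <- function(par0, r, n, x, model, prior = NULL) {
  box <- item_box(model)
  fn <- function(p) {
    a <- p[1]; d <- p[2]; c <- if (model == "3PL") p[3] else 0
    s <- stats::plogis(a * x + d)
    P <- pmin(pmax(c + (1 - c) * s, 1e-12), 1 - 1e-12)
    val <- sum(r * log(P) + (n - r) * log1p(-P))
    if (!is.null(prior)) {
      val <- val + prior_log_density_1(a, prior$slope) +
        prior_log_density_1(d, prior$intercept) +
        (if (model == "3PL") prior_log_density_1(c, prior$guessing) else 0)
    }
    val
  }
  gr <- function(p) {
    a <- p[1]; d <- p[2]; c <- if (model == "3PL") p[3] else 0
    s <- stats::plogis(a * x + d)
    P <- pmin(pmax(c + (1 - c) * s, 1e-12), 1 - 1e-12)
    z <- (r - n * P) / (P * (1 - P))
    ss <- (1 - c) * s * (1 - s)
    g <- c(sum(z * x * ss), sum(z * ss))
    if (model == "3PL") g <- c(g, sum(z * (1 - s)))
    if (!is.null(prior)) {
      g <- g + c(prior_log_density_grad_1(a, prior$slope),
                 prior_log_density_grad_1(d, prior$intercept),
                 if (model == "3PL") prior_log_density_grad_1(c, prior$guessing))
    }
    g
  }
  stats::optim(par0, fn, gr, method = "L-BFGS-B",
               lower = box$lower, upper = box$upper,
               control = list(fnscale = -1, maxit = 100))$par
}

# exact expected complete-data update of one group's (mean, var):
# maximises sum_q n_q log w_q(mean, var) with normalised node weights
mstep_group <- function(par0, nq, quad) {
  fn <- function(p) sum(nq * group_log_weights(quad, p[1], p[2]))
  o <- stats::optim(par0, fn, method = "L-BFGS-B",
                    lower = c(-6, 1e-3), upper = c(6, 100),
                    control = list(fnscale = -1, maxit = 100))
  o$par
}

# ---- polish: direct quasi-Newton on the marginal objective ---------------

# pack/unpack the full free-parameter vector (item params + non-reference
# group params)
pack_free <- function(params, group_params, model) {
  v <- stack_item_params(params, model)
  ng <- nrow(group_params)
  if (ng > 1) {
    for (g in 2:ng) {
      v <- c(v, stats::setNames(c(group_params$mean[g], group_params$var[g]),
                                paste0("group", g, c("_mean", "_var"))))
    }
  }
  v
}

unpack_free <- function(v, items, model, ngroups) {
  npar <- length(item_par_names(model)) * length(items)
  params <- unstack_item_params(v[seq_len(npar)], items, model)
  gp <- tibble::tibble(group = seq_len(ngroups), mean = 0, var = 1,
                       reference = seq_len(ngroups) == 1)
  if (ngroups > 1) {
    rest <- v[-seq_len(npar)]
    gp$mean[-1] <- rest[seq(1, by = 2, length.out = ngroups - 1)]
    gp$var[-1] <- rest[seq(2, by = 2, length.out = ngroups - 1)]
  }
  list(params = params, group_params = gp)
}

# objective (marginal loglik [+ log prior]) and its analytic gradient
marginal_objective <- function(v, rd, model, quad, prior, ngroups) {
  up <- unpack_free(v, rd$items, model, ngroups)
  es <- estep(rd, up$params, up$group_params, quad)
  val <- es$loglik
  if (!is.null(prior)) val <- val + log_prior_density(up$params, prior, model)
  sc <- pattern_scores(rd, up$params, up$group_params, quad, es)
  g_item <- colSums((sc$item * rd$counts))
  grad <- g_item
  if (ngroups > 1) grad <- c(grad, colSums(sc$group * rd$counts))
  if (!is.null(prior)) {
    grad[seq_along(g_item)] <- grad[seq_along(g_item)] +
      log_prior_gradient(up$params, prior, model)
  }
  list(value = val, grad = grad, estep = es)
}

polish_fit <- function(v0, rd, model, quad, prior, ngroups, pgtol = 1e-4,
                       maxit = 500) {
  box <- item_box(model)
  lower <- rep(box$lower, rd$J)
  upper <- rep(box$upper, rd$J)
  if (ngroups > 1) {
    lower <- c(lower, rep(c(-6, 1e-3), ngroups - 1))
    upper <- c(upper, rep(c(6, 100), ngroups - 1))
  }
  # optim calls fn and gr separately at the same point; cache the last
  # evaluation so each iteration costs one E-step, not two
  cache <- new.env(parent = emptyenv())
  eval_at <- function(v) {
    if (!identical(cache$v, v)) {
      cache$res <- marginal_objective(v, rd, model, quad, prior, ngroups)
      cache$v <- v
    }
    cache$res
  }
  fn <- function(v) eval_at(v)$value
  gr <- function(v) eval_at(v)$grad
  proj_norm <- function(v) {
    g <- eval_at(v)$grad
    g[v <= lower + 1e-10 & g < 0] <- 0
    g[v >= upper - 1e-10 & g > 0] <- 0
    max(abs(g))
  }
  # L-BFGS-B line searches can stall short of the optimum; restarting from
  # the stopped point resets the Hessian approximation and recovers
  o <- stats::optim(v0, fn, gr, method = "L-BFGS-B", lower = lower,
                    upper = upper,
                    control = list(fnscale = -1, maxit = maxit,
                                   factr = 1e7, pgtol = pgtol))
  tries <- 1
  while (proj_norm(o$par) > 5 * pgtol && tries < 6) {
    o2 <- stats::optim(o$par, fn, gr, method = "L-BFGS-B", lower = lower,
                       upper = upper,
                       control = list(fnscale = -1, maxit = maxit,
                                      factr = 10, pgtol = pgtol))
    improved <- o2$value > o$value || proj_norm(o2$par) < proj_norm(o$par)
    o <- o2
    tries <- tries + 1
    if (!improved) break
  }
  o$restarts <- tries - 1
  o
}

# ---- user-facing fit ------------------------------------------------------

#' Fit a 2PL or 3PL model by MML or MAP
#'
#' Estimates item parameters by marginal maximum likelihood (MML) or Bayesian
#' maximum-a-posteriori (MAP) estimation, integrating abilities over a fixed
#' quadrature grid.  With `group` given, a multiple-group model is fitted:
#' item parameters are constrained equal across groups while each
#' non-reference group gets its own ability mean and variance (impact), the
#' first group being fixed at N(0, 1).  Group parameters are always estimated
#' by maximum likelihood; the prior applies to item parameters only.
#'
#' Optimisation runs an EM phase (expected-count M-steps per item, exact
#' expected-complete-data updates of the group parameters) followed by a
#' quasi-Newton polish of the marginal log-likelihood (or log-posterior)
#' using the analytic score vector, so converged fits satisfy the score
#' identities: item-parameter score sums vanish at an MML optimum and equal
#' minus the log-prior gradient at a MAP optimum.
#'
#' @param data Data frame holding one row per person and 0/1 item columns.
#' @param items Character vector of item column names; default: all columns
#'   whose name starts with `"item"`.
#' @param model `"2PL"` or `"3PL"`.
#' @param method `"MML"` or `"MAP"`.
#' @param prior A [prior_spec()]; required for MAP, ignored for MML.
#' @param group Optional name of a column in `data` with the person group
#'   labels of the multiple-group (impact) model; `NULL` fits a single group.
#' @param quad A [quadrature()] grid.
#' @param control List of optimiser settings: `em_maxit` (EM cycles before
#'   the polish, default 50), `em_tol` (EM parameter-change tolerance,
#'   default 1e-5), `polish` (logical, default `TRUE`; with `polish = FALSE`
#'   EM runs to `em_tol` with cap `em_maxit_nopolish` = 2000), `pgtol`
#'   (polish gradient tolerance, default 1e-6).
#' @return An object of class `irt_fit`.
#' @examples
#' dat <- sim_dataset(n_persons = 300, n_items = 5, model = "2PL", seed = 1)
#' fit <- fit_irt(dat, model = "2PL", method = "MML")
#' tidy(fit)
#' @export
fit_irt <- function(data, items = NULL, model = c("2PL", "3PL"),
                    method = c("MML", "MAP"), prior = NULL, group = NULL,
                    quad = quadrature(), control = list()) {
  model <- match.arg(model)
  method <- match.arg(method)
  if (method == "MAP" && is.null(prior)) {
    rlang::abort("MAP estimation requires a prior_spec",
                 class = "scoredif_config_error")
  }
  if (method == "MML") prior <- NULL
  ctl <- utils::modifyList(
    list(em_maxit = 50, em_tol = 1e-5, polish = TRUE,
         em_maxit_nopolish = 2000, pgtol = 1e-6), control)

  items <- items %||% grep("^item", names(data), value = TRUE)
  if (length(items) < 1) {
    rlang::abort("no item columns found", class = "scoredif_data_error")
  }
  Y <- as.matrix(data[items])
  if (is.null(group)) {
    g <- rep(1L, nrow(Y)); group_levels <- "all"
  } else {
    gf <- factor(data[[group]])
    g <- as.integer(gf); group_levels <- levels(gf)
  }
  rd <- prep_responses(Y, g)
  ngroups <- length(group_levels)

  # deterministic starts
  pm <- colMeans(Y)
  params <- item_params(a = rep(1, rd$J),
                        d = pmin(pmax(stats::qlogis(pm), -3), 3),
                        c = if (model == "3PL") 0.1 else 0,
                        model = model, item = items)
  group_params <- tibble::tibble(group = seq_len(ngroups), mean = 0, var = 1,
                                 reference = seq_len(ngroups) == 1)

  em_max <- if (ctl$polish) ctl$em_maxit else ctl$em_maxit_nopolish
  trace <- numeric(0)
  delta <- Inf
  iter <- 0
  while (iter < em_max) {
    iter <- iter + 1
    es <- estep(rd, params, group_params, quad)
    trace <- c(trace, es$loglik +
                 if (!is.null(prior)) log_prior_density(params, prior, model) else 0)
    old <- pack_free(params, group_params, model)
    nq_tot <- colSums(es$post * rd$counts)
    rq <- t(rd$Ypat) %*% (es$post * rd$counts)   # J x Q expected correct
    newpar <- as.matrix(params[item_par_names(model)])
    for (j in seq_len(rd$J)) {
      newpar[j, ] <- mstep_item(newpar[j, ], rq[j, ], nq_tot, quad$x, model,
                                prior)
    }
    params$a <- newpar[, 1]; params$d <- newpar[, 2]
    if (model == "3PL") params$c <- newpar[, 3]
    if (ngroups > 1) {
      for (gi in 2:ngroups) {
        ngq <- colSums(es$post[rd$gpat == gi, , drop = FALSE] *
                         rd$counts[rd$gpat == gi])
        gp <- mstep_group(c(group_params$mean[gi], group_params$var[gi]),
                          ngq, quad)
        group_params$mean[gi] <- gp[1]; group_params$var[gi] <- gp[2]
      }
    }
    delta <- max(abs(pack_free(params, group_params, model) - old))
    if (delta < ctl$em_tol) break
  }

  polish_info <- NULL
  if (ctl$polish) {
    o <- polish_fit(pack_free(params, group_params, model), rd, model, quad,
                    prior, ngroups, pgtol = ctl$pgtol)
    up <- unpack_free(o$par, items, model, ngroups)
    params <- up$params; group_params <- up$group_params
    polish_info <- list(convergence = o$convergence, counts = o$counts,
                        restarts = o$restarts, message = o$message)
  }
  es <- estep(rd, params, group_params, quad)
  v_hat <- pack_free(params, group_params, model)
  obj <- marginal_objective(v_hat, rd, model, quad, prior, ngroups)
  # project the gradient onto the box: at an active bound the score identity
  # cannot hold in the raw gradient, only in the projected one
  box <- item_box(model)
  lower <- rep(box$lower, rd$J); upper <- rep(box$upper, rd$J)
  if (ngroups > 1) {
    lower <- c(lower, rep(c(-6, 1e-3), ngroups - 1))
    upper <- c(upper, rep(c(6, 100), ngroups - 1))
  }
  proj <- obj$grad
  at_lower <- v_hat <= lower + 1e-10
  at_upper <- v_hat >= upper - 1e-10
  proj[at_lower & proj < 0] <- 0
  proj[at_upper & proj > 0] <- 0
  grad_norm <- max(abs(proj))
  converged <- if (ctl$polish) grad_norm < 1e-3 else delta < ctl$em_tol
  if (!converged) {
    rlang::abort(
      paste0("estimation did not converge (EM iterations = ", iter,
             ", last parameter change = ", signif(delta, 3),
             ", gradient sup-norm = ", signif(grad_norm, 3), ")"),
      class = "scoredif_convergence_error",
      trace_loglik = trace
    )
  }
  group_params$label <- group_levels

  structure(list(
    params = params, group_params = group_params, model = model,
    method = method, prior = prior, quad = quad,
    data = rd, group_levels = group_levels,
    loglik = es$loglik,
    logpost = if (!is.null(prior)) es$loglik + log_prior_density(params, prior, model) else NULL,
    convergence = list(em_iterations = iter, em_delta = delta,
                       loglik_trace = trace, polish = polish_info,
                       gradient_sup_norm = grad_norm,
                       raw_gradient_sup_norm = max(abs(obj$grad)),
                       active_bounds = names(v_hat)[at_lower | at_upper])
  ), class = "irt_fit")
}

#' Marginal log-likelihood of a response matrix
#'
#' Sums, over persons, the log of the ability-integrated likelihood
#' \eqn{\log \int \prod_j P_j(\theta)^{y_{ij}} (1-P_j(\theta))^{1-y_{ij}}
#' \phi_{g(i)}(\theta)\, d\theta}, approximated on the quadrature grid.
#'
#' @param data Data frame with 0/1 item columns matching `params$item`.
#' @param params An [item_params()] table.
#' @param group_params Tibble with columns `group`, `mean`, `var`; default a
#'   single standard-normal group.
#' @param group Optional group column name in `data` (labels matched in
#'   factor-level order to `group_params` rows).
#' @param quad A [quadrature()] grid.
#' @export
marginal_loglik <- function(data, params, group_params = NULL, group = NULL,
                            quad = quadrature()) {
  Y <- as.matrix(data[params$item])
  g <- if (is.null(group)) rep(1L, nrow(Y)) else as.integer(factor(data[[group]]))
  group_params <- group_params %||%
    tibble::tibble(group = 1L, mean = 0, var = 1)
  storage.mode(Y) <- "double"
  rd <- list(Ypat = Y, gpat = g, counts = rep(1, nrow(Y)), N = nrow(Y),
             J = ncol(Y), items = colnames(Y))
  estep(rd, params, group_params, quad)$loglik
}

#' Posterior quadrature weights per person
#'
#' Row `i` holds the posterior distribution of person `i`'s ability over the
#' quadrature nodes, given their responses and group, at the fitted
#' parameters.  Rows are nonnegative and sum to one.
#'
#' @param fit An [fit_irt()] object.
#' @return An `N x Q` matrix.
#' @export
posterior_ability_weights <- function(fit) {
  es <- estep(fit$data, fit$params, fit$group_params, fit$quad)
  es$post[fit$data$id, , drop = FALSE]
}
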