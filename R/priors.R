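#' Item-parameter prior specifications for MAP estimation
#'
#' A prior spec assigns one distribution per item-parameter class, shared by
#' all items: the slope prior is log-normal (`meanlog`, `varlog`) or normal
#' (`mean`, `var`), the intercept prior is normal, and the pseudo-guessing
#' prior is a beta distribution on (0, 1).  Variances are variances, not
#' standard deviations.
#'
#' Two presets cover the usual analysis choices:
#' * `prior_agreeing()`: slope LN(0, 0.0625) (so the log-slope SD is 0.25),
#'   intercept N(0, 1), guessing Beta(4, 45) — priors that agree with the
#'   distributions item parameters are typically drawn from in simulation
#'   work.  The guessing shape is configurable because Beta(5, 45) is the
#'   matching generating distribution; see the package vignette.
#' * `prior_noninformative()`: slope N(1, 10), intercept N(0, 10), guessing
#'   Beta(1, 1) (flat on (0, 1), zero log-density gradient).
#'
#' @param slope,intercept,guessing Lists describing one distribution each,
#'   e.g. `list(dist = "lognormal", meanlog = 0, varlog = 0.0625)`,
#'   `list(dist = "normal", mean = 0, var = 1)`,
#'   `list(dist = "beta", shape1 = 4, shape2 = 45)`.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(slope, intercept, guessing = list(dist = "beta", shape1 = 1, shape2 = 1)) {
  p <- list(slope = slope, intercept = intercept, guessing = guessing)
  stopifnot(slope$dist %in% c("lognormal", "normal"),
            intercept$dist == "normal",
            guessing$dist == "beta")
  if (slope$dist == "lognormal") stopifnot(slope$varlog > 0) else stopifnot(slope$var > 0)
  stopifnot(intercept$var > 0, guessing$shape1 > 0, guessing$shape2 > 0)
  structure(p, class = "prior_spec")
}

#' @rdname prior_spec
#' @param guessing_shape Length-2 numeric, the beta shapes of the guessing
#'   prior in the agreeing preset.
#' @export
prior_agreeing <- function(guessing_shape = c(4, 45)) {
  prior_spec(
    slope = list(dist = "lognormal", meanlog = 0, varlog = 0.0625),
    intercept = list(dist = "normal", mean = 0, var = 1),
    guessing = list(dist = "beta", shape1 = guessing_shape[1],
                    shape2 = guessing_shape[2])
  )
}

#' @rdname prior_spec
#' @export
prior_noninformative <- function() {
  prior_spec(
    slope = list(dist = "normal", mean = 1, var = 10),
    intercept = list(dist = "normal", mean = 0, var = 10),
    guessing = list(dist = "beta", shape1 = 1, shape2 = 1)
  )
}

# log density of one prior component at x (vectorised)
prior_log_density_1 <- function(x, spec) {
  switch(spec$dist,
    lognormal = stats::dlnorm(x, spec$meanlog, sqrt(spec$varlog), log = TRUE),
    normal    = stats::dnorm(x, spec$mean, sqrt(spec$var), log = TRUE),
    beta      = stats::dbeta(x, spec$shape1, spec$shape2, log = TRUE)
  )
}

# gradient of the log density of one prior component at x (vectorised)
prior_log_density_grad_1 <- function(x, spec) {
  switch(spec$dist,
    lognormal = -1 / x - (log(x) - spec$meanlog) / (x * spec$varlog),
    normal    = -(x - spec$mean) / spec$var,
    beta      = {
      # Beta(1,1) is flat: exact zeros, no boundary issue
      if (spec$shape1 == 1 && spec$shape2 == 1) rep(0, length(x))
      else (spec$shape1 - 1) / x - (spec$shape2 - 1) / (1 - x)
    }
  )
}

prior_component_for <- function(prior, par) {
  switch(par, a = prior$slope, d = prior$intercept, c = prior$guessing)
}

#' Summed log prior density over all items
#'
#' @param params An [item_params()] table.
#' @param prior A [prior_spec()].
#' @param model `"2PL"` or `"3PL"`; under 2PL the guessing prior contributes
#'   nothing.
#' @return The scalar log prior density of the stacked parameter vector.
#' @export
log_prior_density <- function(params, prior, model = attr(params, "model")) {
  ld <- sum(prior_log_density_1(params$a, prior$slope)) +
    sum(prior_log_density_1(params$d, prior$intercept))
  if (model == "3PL") ld <- ld + sum(prior_log_density_1(params$c, prior$guessing))
  ld
}

#' Gradient of the summed log prior density
#'
#' Returns the vector `u_prior`: the derivative of the log prior with respect
#' to the stacked item-parameter vector, in item-major order
#' (`a_1, d_1[, c_1], a_2, ...`) — the same column order as score matrices.
#' At a MAP optimum the case-wise score contributions satisfy
#' \eqn{\sum_i \psi(Y_i;\hat\beta) = -u_\mathrm{prior}(\hat\beta)}.
#'
#' @inheritParams log_prior_density
#' @return Named numeric vector of length (items x free parameters).
#' @export
log_prior_gradient <- function(params, prior, model = attr(params, "model")) {
  check_prior_interior(params, prior, model)
  pars <- item_par_names(model)
  g <- vapply(pars, function(p) {
    prior_log_density_grad_1(params[[p]], prior_component_for(prior, p))
  }, numeric(nrow(params)))
  g <- matrix(g, nrow = nrow(params))
  v <- as.vector(t(g))
  names(v) <- as.vector(t(outer(params$item, pars, paste, sep = "_")))
  v
}

check_prior_interior <- function(params, prior, model) {
  if (any(params$a <= 0) && prior$slope$dist == "lognormal") {
    rlang::abort("slope on the boundary of the log-normal prior support",
                 class = "scoredif_boundary")
  }
  if (model == "3PL") {
    gp <- prior$guessing
    flat <- gp$shape1 == 1 && gp$shape2 == 1
    if (!flat && any(params$c <= 0 | params$c >= 1)) {
      rlang::abort("pseudo-guessing on the boundary of the beta prior support",
                   class = "scoredif_boundary")
    }
  }
  invisible(NULL)
}
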