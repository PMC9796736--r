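#' Item response probability for the 2PL/3PL model
#'
#' Evaluates the three-parameter logistic response function in
#' slope--intercept form,
#' \deqn{P(Y = 1 \mid \theta) = (c + \Delta c) +
#'   \frac{1 - c - \Delta c}{1 + \exp\{-[(a + \Delta a)\theta + (d + \Delta d)]\}},}
#' where \eqn{a} is a slope (discrimination), \eqn{d} an intercept (easiness,
#' logit units) and \eqn{c} a pseudo-guessing lower asymptote.  The 2PL model
#' is the restriction \eqn{c = \Delta c = 0}.  The delta terms are DIF offsets
#' used only when generating data; fitted models never carry them.
#'
#' Note the linear predictor is \eqn{a\theta + d}, not the
#' difficulty form \eqn{a(\theta - b)}.
#'
#' @param theta Numeric vector of abilities.
#' @param a,d,c Item slope (> 0), intercept, and pseudo-guessing in `[0, 1)`.
#' @param delta_a,delta_d,delta_c DIF offsets added to the respective
#'   parameters (default 0).
#' @return Numeric vector of response probabilities, recycled over inputs.
#' @examples
#' response_probability(0, a = 1, d = 0)            # 0.5
#' response_probability(1, a = 2, d = -1)           # plogis(1)
#' response_probability(-Inf, a = 1, d = 0, c = 0.1, delta_c = 0.1)  # 0.2
#' @export
response_probability <- function(theta, a, d, c = 0,
                                 delta_a = 0, delta_d = 0, delta_c = 0) {
  a_eff <- a + delta_a
  c_eff <- c + delta_c
  if (any(a_eff <= 0)) {
    rlang::abort("effective slope a + delta_a must be > 0",
                 class = "scoredif_invalid_parameter")
  }
  if (any(c_eff < 0 | c_eff >= 1)) {
    rlang::abort("effective pseudo-guessing c + delta_c must lie in [0, 1)",
                 class = "scoredif_invalid_parameter")
  }
  c_eff + (1 - c_eff) * stats::plogis(a_eff * theta + (d + delta_d))
}

#' Construct an item-parameter table
#'
#' @param a,d,c Numeric vectors of slopes, intercepts and pseudo-guessing
#'   values (recycled to a common length).
#' @param model `"2PL"` or `"3PL"`; under 2PL `c` is forced to zero and the
#'   guessing parameter is excluded from the stacked parameter vector.
#' @param item Optional item names (default `item1..itemJ`).
#' @return A tibble with columns `item`, `a`, `d`, `c` and a `model`
#'   attribute; class `item_params`.
#' @export
item_params <- function(a, d, c = 0, model = c("2PL", "3PL"), item = NULL) {
  model <- match.arg(model)
  if (model == "2PL" && any(c != 0)) {
    rlang::abort("2PL requires c = 0; use model = \"3PL\" for guessing",
                 class = "scoredif_invalid_parameter")
  }
  n <- max(length(a), length(d), length(c))
  out <- tibble::tibble(
    item = item %||% paste0("item", seq_len(n)),
    a = rep_len(as.numeric(a), n),
    d = rep_len(as.numeric(d), n),
    c = if (model == "2PL") 0 else rep_len(as.numeric(c), n)
  )
  validate_item_params(out, model)
  structure(out, model = model, class = c("item_params", class(out)))
}

validate_item_params <- function(params, model) {
  if (any(params$a <= 0)) {
    rlang::abort("slopes must be > 0", class = "scoredif_invalid_parameter")
  }
  if (any(params$c < 0 | params$c >= 1)) {
    rlang::abort("pseudo-guessing must lie in [0, 1)",
                 class = "scoredif_invalid_parameter")
  }
  if (model == "2PL" && any(params$c != 0)) {
    rlang::abort("2PL requires c = 0", class = "scoredif_invalid_parameter")
  }
  invisible(params)
}

# Names of the free parameters of one item under a model, in stacked order.
item_par_names <- function(model) {
  if (model == "2PL") c("a", "d") else c("a", "d", "c")
}

# Stacked item-major parameter vector (a_1, d_1[, c_1], a_2, ...) with
# names "<item>_<par>"; the order every score matrix column follows.
stack_item_params <- function(params, model = attr(params, "model")) {
  pars <- item_par_names(model)
  v <- as.vector(t(as.matrix(params[pars])))
  names(v) <- as.vector(t(outer(params$item, pars, paste, sep = "_")))
  v
}

unstack_item_params <- function(v, items, model) {
  pars <- item_par_names(model)
  m <- matrix(v, nrow = length(items), byrow = TRUE,
              dimnames = list(NULL, pars))
  out <- tibble::as_tibble(m)
  if (model == "2PL") out$c <- 0
  out <- tibble::tibble(item = items, a = out$a, d = out$d, c = out$c)
  structure(out, model = model, class = c("item_params", class(out)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
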