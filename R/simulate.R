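# Synthetic data with the simulation study's generating process: 2PL/3PL
# responses, Bernoulli(.5) two-category or uniform(20, 70) continuous
# covariates, optional impact N(-0.5, 1) / N(0.5, 1) across the covariate
# split, and DIF deltas on one fifth of the items.

#' Draw item parameters from the generating distributions
#'
#' Slopes are log-normal LN(0, 0.0625) (log-scale variance 0.0625),
#' intercepts N(0, 1); under the 3PL, pseudo-guessing values are
#' Beta(5, 45) (mean 0.1), otherwise exactly 0.  Uses the current RNG state.
#'
#' @param n_items Number of items.
#' @param model `"2PL"` or `"3PL"`.
#' @param guessing_shape Beta shapes of the guessing distribution.
#' @return An [item_params()] tibble.
#' @export
sim_item_params <- function(n_items, model = c("2PL", "3PL"),
                            guessing_shape = c(5, 45)) {
  model <- match.arg(model)
  item_params(
    a = stats::rlnorm(n_items, 0, sqrt(0.0625)),
    d = stats::rnorm(n_items, 0, 1),
    c = if (model == "3PL") {
      stats::rbeta(n_items, guessing_shape[1], guessing_shape[2])
    } else 0,
    model = model
  )
}

#' Draw person covariates, impact sides and abilities
#'
#' Categorical covariates assign each person to one of two categories with
#' probability .5; continuous covariates are uniform on (20, 70), split at 35
#' into a reference (< 35) and focal (>= 35) side, emulating a cohort
#' covariate like age.  With `impact = TRUE` abilities are N(-0.5, 1) on the
#' reference side and N(0.5, 1) on the focal side; otherwise N(0, 1)
#' throughout.  Uses the current RNG state.
#'
#' @param n Number of persons.
#' @param covariate `"categorical"` or `"continuous"`.
#' @param impact Simulate an ability difference between the sides?
#' @return Tibble with `covariate`, `side` (factor reference/focal; the
#'   focal side receives DIF deltas and, with impact, the higher ability),
#'   and `theta`.
#' @export
sim_persons <- function(n, covariate = c("categorical", "continuous"),
                        impact = FALSE) {
  covariate <- match.arg(covariate)
  if (covariate == "categorical") {
    side <- stats::rbinom(n, 1, 0.5)          # 0 = first category (reference)
    cov_vals <- factor(ifelse(side == 0, "1", "2"), levels = c("1", "2"))
  } else {
    cov_vals <- stats::runif(n, 20, 70)
    side <- as.integer(cov_vals >= 35)
  }
  mu <- if (impact) ifelse(side == 0, -0.5, 0.5) else 0
  tibble::tibble(
    covariate = cov_vals,
    side = factor(ifelse(side == 0, "reference", "focal"),
                  levels = c("reference", "focal")),
    theta = stats::rnorm(n, mu, 1)
  )
}

#' Plant DIF effects on one fifth of the items
#'
#' Selects `round(n_items / 5)` items uniformly at random and sets the delta
#' of the targeted parameter to 0.3 (slope), 0.6 (intercept) or 0.1
#' (pseudo-guessing).  `"unbalanced"` gives every selected item `+delta`
#' (favouring the focal — with impact, more able — side); `"balanced"` gives
#' half of them `+delta` and half `-delta`, the extra item of an odd split
#' getting `+delta`, with the sign assignment randomised over the selected
#' items.  Deltas apply to the focal side only, at data-generation time.
#'
#' @param params An [item_params()] tibble.
#' @param target `"slope"`, `"intercept"` or `"guessing"`.
#' @param direction `"balanced"` or `"unbalanced"`.
#' @return `params` with added `delta_a`, `delta_d`, `delta_c`, `dif`
#'   columns.
#' @export
sim_dif <- function(params, target = c("slope", "intercept", "guessing"),
                    direction = c("balanced", "unbalanced")) {
  target <- match.arg(target)
  direction <- match.arg(direction)
  model <- attr(params, "model")
  if (target == "guessing" && model == "2PL") {
    rlang::abort("guessing DIF requires the 3PL model",
                 class = "scoredif_config_error")
  }
  J <- nrow(params)
  n_dif <- max(1L, round(J / 5))
  dif_items <- sort(sample.int(J, n_dif))
  delta <- switch(target, slope = 0.3, intercept = 0.6, guessing = 0.1)
  signs <- if (direction == "unbalanced") {
    rep(1, n_dif)
  } else {
    sample(rep(c(1, -1), c(ceiling(n_dif / 2), floor(n_dif / 2))))
  }
  params$delta_a <- params$delta_d <- params$delta_c <- rep(0, J)
  col <- switch(target, slope = "delta_a", intercept = "delta_d",
                guessing = "delta_c")
  params[[col]][dif_items] <- signs * delta
  params$dif <- seq_len(J) %in% dif_items
  if (any(params$a + params$delta_a <= 0) ||
      any(params$c + params$delta_c < 0 | params$c + params$delta_c >= 1)) {
    rlang::abort("DIF deltas push parameters outside their admissible range",
                 class = "scoredif_invalid_parameter")
  }
  params
}

#' Generate one synthetic response dataset
#'
#' Draws item parameters, persons and (optionally) DIF deltas, then samples
#' binary responses `Y_ij ~ Bernoulli(P(theta_i))`, with the deltas applied
#' only on the focal side of the covariate (second category, or covariate
#' >= 35).  The result is fully determined by `(seed, replicate)`.
#'
#' @param n_persons,n_items Sample sizes.
#' @param model `"2PL"` or `"3PL"`.
#' @param covariate `"categorical"` or `"continuous"`.
#' @param impact Ability difference between the covariate sides?
#' @param dif `"none"`, `"slope"`, `"intercept"` or `"guessing"`.
#' @param direction `"balanced"` or `"unbalanced"` (ignored for
#'   `dif = "none"`).
#' @param seed Master seed.
#' @param replicate Replicate index; different replicates under the same
#'   seed give independent datasets.
#' @param params Optional pre-drawn [item_params()] (possibly with delta
#'   columns) to reuse; skips drawing items and DIF.
#' @return A tibble with columns `item1..itemJ`, `covariate`, `side` and
#'   `theta`, carrying the generating truth in attribute `"truth"`
#'   (`params` incl. deltas, `dif_items`).
#' @examples
#' dat <- sim_dataset(200, 10, model = "2PL", dif = "intercept", seed = 1)
#' attr(dat, "truth")$params
#' @export
sim_dataset <- function(n_persons, n_items = 10, model = c("2PL", "3PL"),
                        covariate = c("categorical", "continuous"),
                        impact = FALSE,
                        dif = c("none", "slope", "intercept", "guessing"),
                        direction = c("balanced", "unbalanced"),
                        seed = NULL, replicate = 1, params = NULL) {
  model <- match.arg(model)
  covariate <- match.arg(covariate)
  dif <- match.arg(dif)
  direction <- match.arg(direction)
  with_preserved_seed(if (is.null(seed)) NULL else mix_seed(seed, replicate), {
    if (is.null(params)) {
      params <- sim_item_params(n_items, model)
      if (dif != "none") params <- sim_dif(params, dif, direction)
    }
    if (!"delta_a" %in% names(params)) {
      params$delta_a <- params$delta_d <- params$delta_c <- 0
      params$dif <- FALSE
    }
    persons <- sim_persons(n_persons, covariate, impact)
    focal <- persons$side == "focal"
    P <- matrix(0, n_persons, nrow(params))
    for (j in seq_len(nrow(params))) {
      P[, j] <- response_probability(
        persons$theta, params$a[j], params$d[j], params$c[j],
        delta_a = focal * params$delta_a[j],
        delta_d = focal * params$delta_d[j],
        delta_c = focal * params$delta_c[j]
      )
    }
    Y <- matrix(stats::rbinom(length(P), 1, P), nrow(P), ncol(P))
    colnames(Y) <- paste0("item", seq_len(ncol(Y)))
    out <- dplyr::bind_cols(tibble::as_tibble(Y), persons)
    attr(out, "truth") <- list(params = params,
                               dif_items = which(params$dif),
                               model = model, impact = impact)
    out
  })
}
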