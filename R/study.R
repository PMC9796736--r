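# Monte Carlo size/power study driver over the simulation design grid.

#' Build a study design grid
#'
#' Crosses the supplied condition levels into one row per study cell.
#' Defaults mirror the simulation design this package emulates; any subset
#' can be selected.
#'
#' @param model,n_persons,n_items,covariate,impact,dif,direction,estimation,engine
#'   Vectors of condition levels; `estimation` is one of `"MML"`,
#'   `"MAP-agreeing"`, `"MAP-noninformative"`, `engine` is `"pooled"`
#'   (asymptotic) or `"simulation"`.
#' @return Tibble of cells; incompatible rows (guessing DIF under 2PL) are
#'   dropped.
#' @export
study_grid <- function(model = c("2PL", "3PL"),
                       n_persons = c(500, 1000, 2000, 5000),
                       n_items = c(10, 30),
                       covariate = c("categorical", "continuous"),
                       impact = c(FALSE, TRUE),
                       dif = c("none", "slope", "intercept", "guessing"),
                       direction = "unbalanced",
                       estimation = c("MML", "MAP-agreeing",
                                      "MAP-noninformative"),
                       engine = c("pooled", "simulation")) {
  g <- tidyr::expand_grid(
    model = model, n_persons = n_persons, n_items = n_items,
    covariate = covariate, impact = impact, dif = dif,
    direction = direction, estimation = estimation, engine = engine
  )
  dplyr::filter(g, !(.data$model == "2PL" & .data$dif == "guessing"))
}

study_prior <- function(estimation, agreeing_guess = c(4, 45)) {
  switch(estimation,
         "MML" = NULL,
         "MAP-agreeing" = prior_agreeing(agreeing_guess),
         "MAP-noninformative" = prior_noninformative(),
         rlang::abort(paste0("unknown estimation method: ", estimation),
                      class = "scoredif_config_error"))
}

# one study replicate: generate, fit, test; returns the p-value
study_replicate <- function(cell, rep_seed, sim_R, agreeing_guess) {
  dat <- sim_dataset(
    n_persons = cell$n_persons, n_items = cell$n_items, model = cell$model,
    covariate = cell$covariate, impact = cell$impact,
    dif = cell$dif, direction = cell$direction, seed = rep_seed
  )
  prior <- study_prior(cell$estimation, agreeing_guess)
  res <- dif_test(
    dat, covariate = "covariate",
    group = if (cell$impact) "side" else NULL,
    model = cell$model,
    method = if (is.null(prior)) "MML" else "MAP", prior = prior,
    engine = if (cell$engine == "pooled") "asymptotic" else "simulation",
    R = sim_R, seed = mix_seed(rep_seed, 1)
  )
  res$result$p
}

cell_seed_base <- function(seed, cell) {
  desc <- paste(unlist(cell), collapse = "|")
  mix_seed(seed, sum(utf8ToInt(desc) * seq_along(utf8ToInt(desc))))
}

#' Run the Monte Carlo size/power study
#'
#' For every cell of the grid, generates `reps` datasets, runs the full
#' fit-score-test pipeline and tabulates the fraction of p-values below
#' `alpha`.  Per-replicate RNG streams are derived from (seed, cell
#' descriptor, replicate index), so each cell is reproducible bit-for-bit in
#' isolation and results are independent of `jobs`.
#'
#' @param grid A [study_grid()] tibble (or any tibble with its columns).
#' @param reps Replicates per cell.
#' @param seed Master seed.
#' @param alpha Rejection level tabulated (reporting only; all p-values feed
#'   the rate).
#' @param sim_R Reference-distribution replicates of the simulation engine.
#' @param agreeing_guess Beta shapes of the agreeing guessing prior
#'   (the generating distribution stays Beta(5, 45)).
#' @param jobs Parallel workers (forked; results identical for any value).
#' @param verbose Log per-cell progress to stderr.
#' @return The grid with added columns `reps`, `failures`, `rejections`,
#'   `rate` and `mc_se` (binomial Monte Carlo standard error); failed fits
#'   are counted and excluded from the denominator.
#' @export
run_study <- function(grid, reps = 100, seed = 1, alpha = 0.05, sim_R = 300,
                      agreeing_guess = c(4, 45), jobs = 1, verbose = FALSE) {
  if (reps < 1) {
    rlang::abort("reps must be positive", class = "scoredif_config_error")
  }
  rows <- lapply(seq_len(nrow(grid)), function(ci) {
    cell <- as.list(grid[ci, ])
    base <- cell_seed_base(seed, cell)
    t0 <- Sys.time()
    one <- function(r) {
      tryCatch(study_replicate(cell, mix_seed(base, r), sim_R,
                               agreeing_guess),
               error = function(e) NA_real_)
    }
    ps <- if (jobs > 1) {
      unlist(parallel::mclapply(seq_len(reps), one, mc.cores = jobs,
                                mc.preschedule = TRUE))
    } else {
      vapply(seq_len(reps), one, numeric(1))
    }
    ok <- sum(!is.na(ps))
    rej <- sum(ps < alpha, na.rm = TRUE)
    rate <- if (ok > 0) rej / ok else NA_real_
    if (verbose) {
      message(sprintf("cell %d/%d: rate = %.3f (%d/%d, %.1fs)",
                      ci, nrow(grid), rate, rej, ok,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    }
    tibble::tibble(reps = reps, failures = reps - ok, rejections = rej,
                   rate = rate,
                   mc_se = if (ok > 0) sqrt(rate * (1 - rate) / ok) else NA_real_)
  })
  dplyr::bind_cols(grid, dplyr::bind_rows(rows))
}
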