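# Estimation: parameter recovery, posterior weights, marginal likelihood
# and the multiple-group (impact) model.

test_that("MML recovers 2PL generating parameters and MAP shrinks slopes", {
  dat <- sim_dataset(5000, 10, model = "2PL", seed = 301)
  truth <- attr(dat, "truth")$params
  fit <- fit_irt(dat, model = "2PL", method = "MML")
  est <- tidy(fit)
  expect_lte(sqrt(mean((est$a - truth$a)^2)), 0.1)
  expect_lte(sqrt(mean((est$d - truth$d)^2)), 0.1)

  fit_map <- fit_irt(dat, model = "2PL", method = "MAP",
                     prior = prior_agreeing())
  est_map <- tidy(fit_map)
  # the agreeing slope prior has median exp(0) = 1: MAP pulls slopes toward it
  expect_lte(mean(abs(est_map$a - 1)), mean(abs(est$a - 1)))
  # MAP objective decomposes into marginal loglik + log prior
  expect_equal(fit_map$logpost,
               fit_map$loglik + log_prior_density(fit_map$params,
                                                  fit_map$prior, "2PL"),
               tolerance = 1e-10)
})

test_that("posterior ability weights are normalised and ordered by evidence", {
  dat <- sim_dataset(400, 8, model = "2PL", seed = 302)
  fit <- fit_irt(dat, model = "2PL", method = "MML")
  W <- posterior_ability_weights(fit)
  expect_equal(dim(W), c(400L, fit$quad$n))
  expect_true(all(W >= 0))
  expect_equal(rowSums(W), rep(1, 400), tolerance = 1e-12)
  # a person answering everything correctly sits above one missing everything
  x <- fit$quad$x
  Y <- fit$data$Y
  hi <- which(rowSums(Y) == max(rowSums(Y)))[1]
  lo <- which(rowSums(Y) == min(rowSums(Y)))[1]
  expect_gt(sum(W[hi, ] * x), sum(W[lo, ] * x))
})

test_that("an uninformative item leaves the prior weights untouched", {
  # single item with a ~ 0: flat likelihood, posterior = prior weights
  rd <- scoredif:::prep_responses(matrix(c(1, 0), 2, 1,
                                         dimnames = list(NULL, "item1")),
                                  c(1L, 1L))
  params <- item_params(a = 1e-6, d = 0, model = "2PL")
  gp <- tibble::tibble(group = 1L, mean = 0, var = 1)
  es <- scoredif:::estep(rd, params, gp, quadrature())
  prior_w <- exp(scoredif:::group_log_weights(quadrature(), 0, 1))
  expect_equal(es$post[1, ], prior_w, tolerance = 1e-5)
})

test_that("marginal log-likelihood matches a dense-grid oracle and is additive", {
  params <- item_params(a = 1, d = 0, model = "2PL")
  one <- tibble::tibble(item1 = 1)
  ll <- marginal_loglik(one, params)
  oracle <- dense_person_loglik(1, as.data.frame(params))
  expect_equal(ll, oracle, tolerance = 1e-6)
  expect_gt(ll, log(0.5) - 0.3)
  expect_lt(ll, log(0.5) + 0.3)

  dat <- sim_dataset(50, 6, model = "3PL", seed = 303)
  truth <- attr(dat, "truth")$params
  p6 <- item_params(truth$a, truth$d, truth$c, model = "3PL")
  ll1 <- marginal_loglik(dat, p6)
  ll2 <- marginal_loglik(dplyr::bind_rows(dat, dat), p6)
  expect_equal(ll2, 2 * ll1, tolerance = 1e-10)
})

test_that("EM iterations never decrease the objective", {
  dat <- sim_dataset(800, 10, model = "3PL", seed = 304)
  fit <- fit_irt(dat, model = "3PL", method = "MAP", prior = prior_agreeing())
  tr <- fit$convergence$loglik_trace
  expect_gte(length(tr), 3)
  expect_true(all(diff(tr) > -1e-8))
})

test_that("impact model recovers the group ability difference", {
  # identical generating distributions: second group estimated near N(0, 1)
  dat0 <- sim_dataset(5000, 10, model = "2PL", covariate = "categorical",
                      impact = FALSE, seed = 305)
  f0 <- fit_irt(dat0, model = "2PL", method = "MML", group = "side")
  expect_lt(abs(f0$group_params$mean[2]), 0.1)
  expect_lt(abs(f0$group_params$var[2] - 1), 0.15)

  # impact N(-0.5,1)/N(0.5,1) with reference fixed at N(0,1): only the
  # difference is identified, so the second group lands near mean 1
  dat1 <- sim_dataset(5000, 10, model = "2PL", covariate = "categorical",
                      impact = TRUE, seed = 306)
  f1 <- fit_irt(dat1, model = "2PL", method = "MML", group = "side")
  expect_lt(abs(f1$group_params$mean[2] - 1.0), 0.1)
})

test_that("data and configuration errors are caught", {
  dat <- sim_dataset(100, 5, model = "2PL", seed = 307)
  expect_error(fit_irt(dat, model = "2PL", method = "MAP"),
               class = "scoredif_config_error")
  bad <- dat
  bad$item1 <- 1                       # degenerate item
  expect_error(fit_irt(bad, model = "2PL", method = "MML"),
               class = "scoredif_data_error")
  bad2 <- dat
  bad2$item2[5] <- NA
  expect_error(fit_irt(bad2, model = "2PL", method = "MML"),
               class = "scoredif_data_error")
})
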