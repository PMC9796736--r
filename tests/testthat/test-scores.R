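# Case-wise scores, centring, covariance estimation and the cumulative
# process construction.

test_that("case-wise scores are the gradient of each person's marginal loglik", {
  dat <- sim_dataset(300, 5, model = "2PL", seed = 401)
  fit <- fit_irt(dat, model = "2PL", method = "MML")
  S <- score_contributions(fit)
  expect_s3_class(S, "score_matrix")
  expect_identical(attr(S, "state"), "raw")
  expect_equal(dim(S), c(300L, 10L))
  # finite differences of the person-wise marginal log-likelihood in the
  # stacked item parameters reproduce each score row
  v0 <- scoredif:::stack_item_params(fit$params)
  for (i in c(1, 57, 300)) {
    fd <- fd_gradient(function(v) {
      p <- scoredif:::unstack_item_params(v, fit$params$item, "2PL")
      marginal_loglik(dat[i, ], p, quad = fit$quad)
    }, unname(v0))
    expect_equal(unname(S[i, ]), fd, tolerance = 1e-5)
  }
})

test_that("score sums satisfy the MML and MAP optimality identities", {
  dat <- sim_dataset(600, 6, model = "2PL", seed = 402)
  f_mml <- fit_irt(dat, model = "2PL", method = "MML")
  expect_lt(max(abs(colSums(score_contributions(f_mml)))), 1e-3)

  f_map <- fit_irt(dat, model = "2PL", method = "MAP",
                   prior = prior_agreeing())
  u <- log_prior_gradient(f_map$params, f_map$prior)
  expect_lt(max(abs(colSums(score_contributions(f_map)) + u)), 1e-3)
})

test_that("centring zeroes column sums and is idempotent", {
  dat <- sim_dataset(200, 4, model = "2PL", seed = 403)
  fit <- fit_irt(dat, model = "2PL", method = "MAP",
                 prior = prior_agreeing())
  S <- center_scores(score_contributions(fit))
  expect_identical(attr(S, "state"), "centered")
  expect_lt(max(abs(colSums(S))), 1e-10)
  expect_equal(unclass(center_scores(S)), unclass(S))
})

test_that("covariance estimators use divisor N and global-mean centring", {
  set.seed(404)
  raw <- matrix(rnorm(120 * 3), 120, 3,
                dimnames = list(NULL, c("p1", "p2", "p3")))
  g <- rep(c("A", "B"), each = 60)
  Sc <- center_scores(structure(raw, state = "raw",
                                class = c("score_matrix", "matrix", "array")))
  Vp <- score_covariance(Sc, mode = "pooled")
  expect_equal(Vp$V, crossprod(unclass(Sc)) / 120)
  expect_equal(Vp$inv_sqrt %*% Vp$V %*% Vp$inv_sqrt, diag(3),
               tolerance = 1e-10, ignore_attr = TRUE)

  Vg <- score_covariance(Sc, mode = "groupwise", groups = g)
  SA <- unclass(Sc)[g == "A", ]                # globally centred rows
  expect_equal(Vg$V[["A"]], crossprod(SA) / 60)
  # raw scores must be centred first
  expect_error(score_covariance(structure(raw, state = "raw",
                                          class = c("score_matrix", "matrix",
                                                    "array"))),
               class = "scoredif_state_error")
  expect_error(score_covariance(Sc, mode = "groupwise"),
               class = "scoredif_config_error")
})

test_that("a collinear score column raises a singularity error naming it", {
  set.seed(405)
  raw <- matrix(rnorm(80), 80, 1)
  raw <- cbind(raw, 2 * raw)
  colnames(raw) <- c("item1_a", "item1_d")
  Sc <- center_scores(structure(raw, state = "raw",
                                class = c("score_matrix", "matrix", "array")))
  expect_error(score_covariance(Sc, mode = "pooled"),
               class = "scoredif_singular", regexp = "item1_")
})

test_that("the process matches a hand-worked two-person example", {
  # scores (+1, -1): centred already, V = 1, so Psi = (0, 1/sqrt(2), 0)
  S <- matrix(c(1, -1), 2, 1, dimnames = list(NULL, "item1_a"))
  pr <- process_from_scores(S, covariate = c(10, 20))
  expect_equal(as.vector(pr$psi), c(0, 1 / sqrt(2), 0))
  expect_equal(pr$t, c(0, 0.5, 1))
  # reversing the covariate order flips the interior of the path
  pr2 <- process_from_scores(S, covariate = c(20, 10))
  expect_equal(as.vector(pr2$psi), c(0, -1 / sqrt(2), 0))
})

test_that("pooled decorrelation ties the path down at t = 1", {
  set.seed(406)
  S <- matrix(rnorm(500 * 4), 500, 4,
              dimnames = list(NULL, paste0("p", 1:4)))
  pr <- process_from_scores(S, covariate = runif(500))
  expect_lt(max(abs(pr$psi[501, ])), 1e-10)
  # decorrelated increments have identity covariance
  incr <- apply(pr$psi, 2, diff) * sqrt(500)
  expect_equal(crossprod(incr) / 500, diag(4), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("persons are ordered by the covariate with stable ties", {
  S <- matrix(c(1, 2, 4, 8), 4, 1, dimnames = list(NULL, "x"))
  cvt <- c(3, 1, 2, 1)
  pr <- process_from_scores(S, covariate = cvt)
  expect_equal(pr$covariate, c(1, 1, 2, 3))
  # rows with covariate 1 keep original order (persons 2 then 4)
  d <- diff(pr$psi[, 1]) * sqrt(4)
  cS <- as.vector(scale(S, scale = FALSE))
  Vs <- 1 / sqrt(mean(cS^2))
  expect_equal(d, cS[c(2, 4, 3, 1)] * Vs)
})

test_that("tidy and autoplot expose the process in tidy form", {
  set.seed(407)
  S <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("p1", "p2")))
  pr <- process_from_scores(S, covariate = seq_len(30),
                            mode = "groupwise",
                            groups = rep(c("r", "f"), 15))
  td <- tidy(pr)
  expect_named(td, c("t", "component", "value", "group"))
  expect_equal(nrow(td), 2 * 31)
  expect_setequal(unique(td$component), c("p1", "p2"))
  gg <- ggplot2::autoplot(pr)
  expect_s3_class(gg, "ggplot")
})
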