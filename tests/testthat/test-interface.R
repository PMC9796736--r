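# End-to-end dif_test() workflow, tidy/glance accessors, file IO and the
# command-line interface.

fixture_path <- function() {
  system.file("extdata", "responses_null_n500.csv", package = "scoredif")
}

# the category labels "1"/"2" come back numeric from CSV; restore the factor
read_fixture <- function() {
  dat <- read_responses(fixture_path())
  dat$covariate <- factor(dat$covariate)
  dat
}

test_that("dif_test runs end to end on a categorical covariate", {
  dat <- read_fixture()
  res <- dif_test(dat, covariate = "covariate", model = "2PL",
                  method = "MML")
  expect_s3_class(res, "dif_test")
  expect_identical(res$result$statistic, "LM_uo")   # auto on a factor
  expect_identical(res$result$engine, "asymptotic")
  expect_gt(res$result$p, 0)
  expect_lte(res$result$p, 1)
  td <- tidy(res)
  expect_named(td, c("statistic", "value", "p.value", "engine", "R", "k",
                     "N", "m"))
  expect_equal(td$k, 20)                            # 10 items x (a, d)
  expect_equal(td$N, 500)
  expect_equal(td$m, 2)
  gl <- glance(res)
  expect_true(all(c("p.value", "model", "method", "logLik") %in% names(gl)))
  expect_output(print(res), "LM_uo")
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
})

test_that("statistic defaults and guards follow the covariate type", {
  dat <- sim_dataset(400, 5, covariate = "continuous", seed = 32)
  res <- dif_test(dat, covariate = "covariate", model = "2PL",
                  method = "MML")
  expect_identical(res$result$statistic, "DM")
  expect_error(dif_test(dat, covariate = "covariate", statistic = "lmuo",
                        model = "2PL", method = "MML", fit = res$fit),
               class = "scoredif_config_error")
  expect_error(dif_test(dat, covariate = "nope", model = "2PL"),
               class = "scoredif_config_error")
})

test_that("both engines detect planted intercept DIF", {
  dat <- sim_dataset(1500, 10, model = "2PL", covariate = "categorical",
                     dif = "intercept", direction = "unbalanced", seed = 33)
  asy <- dif_test(dat, covariate = "covariate", model = "2PL",
                  method = "MML")
  expect_lt(asy$result$p, 0.05)
  sim <- dif_test(dat, covariate = "covariate", model = "2PL",
                  method = "MML", engine = "simulation", R = 300,
                  seed = 1, fit = asy$fit)
  expect_lt(sim$result$p, 0.05)
})

test_that("a pre-computed fit is reused unchanged", {
  dat <- read_fixture()
  fit <- fit_irt(dat, model = "2PL", method = "MML")
  r1 <- dif_test(dat, covariate = "covariate", model = "2PL",
                 method = "MML")
  r2 <- dif_test(dat, covariate = "covariate", model = "2PL",
                 method = "MML", fit = fit)
  expect_equal(r1$result$value, r2$result$value)
  expect_equal(r1$result$p, r2$result$p)
})

test_that("the simulation engine with a group column uses groupwise covariances", {
  dat <- sim_dataset(600, 5, model = "2PL", covariate = "categorical",
                     impact = TRUE, seed = 34)
  res <- dif_test(dat, covariate = "covariate", group = "side",
                  model = "2PL", method = "MML", engine = "simulation",
                  R = 200, seed = 2)
  expect_identical(res$process$mode, "groupwise")
  expect_equal(nrow(res$fit$group_params), 2L)
  # asymptotic route stays pooled even with a group column
  res2 <- dif_test(dat, covariate = "covariate", group = "side",
                   model = "2PL", method = "MML", fit = res$fit)
  expect_identical(res2$process$mode, "pooled")
})

test_that("response IO round-trips and validates", {
  dat <- sim_dataset(40, 4, seed = 35)
  f <- withr::local_tempfile(fileext = ".csv")
  write_responses(dat, f)
  back <- read_responses(f)
  expect_equal(as.matrix(back[paste0("item", 1:4)]),
               as.matrix(dat[paste0("item", 1:4)]))
  bad <- dat
  bad$item1[3] <- 2
  fb <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad, fb)
  expect_error(read_responses(fb), class = "scoredif_data_error")
})

test_that("fit and test JSON exports carry a complete audit trail", {
  dat <- read_fixture()
  res <- dif_test(dat, covariate = "covariate", model = "2PL",
                  method = "MML", engine = "simulation", R = 150, seed = 9)
  ft <- withr::local_tempfile(fileext = ".json")
  tt <- withr::local_tempfile(fileext = ".json")
  pc <- withr::local_tempfile(fileext = ".csv")
  write_fit_json(res$fit, ft)
  write_test_json(res, tt)
  write_process_csv(res$process, pc)
  fit_json <- jsonlite::read_json(ft)
  expect_identical(fit_json$model, "2PL")
  expect_length(fit_json$items, 10)
  expect_true(is.numeric(fit_json$convergence$gradient_sup_norm))
  test_json <- jsonlite::read_json(tt)
  expect_identical(test_json$statistic, "LM_uo")
  expect_identical(test_json$seed, 9L)
  expect_equal(test_json$R, 150L)
  expect_equal(test_json$p, res$result$p)
  proc <- readr::read_csv(pc, show_col_types = FALSE)
  expect_named(proc, c("t", "component", "value"))
  expect_equal(nrow(proc), 20 * 501)
})

test_that("the CLI dispatches simulate and test subcommands", {
  dir <- withr::local_tempdir()
  out1 <- file.path(dir, "sim")
  suppressMessages(scoredif_main(c(
    "simulate", "--n-persons", "300", "--n-items", "5", "--seed", "5",
    "--out", out1
  )))
  resp <- paste0(out1, "_responses.csv")
  expect_true(file.exists(resp))
  out2 <- file.path(dir, "run")
  res <- suppressMessages(scoredif_main(c(
    "test", "--input", resp, "--covariate", "covariate",
    "--engine", "simulation", "--replications", "150",
    "--seed", "3", "--out", out2
  )))
  expect_s3_class(res, "dif_test")
  expect_true(file.exists(paste0(out2, "_test.json")))
  expect_true(file.exists(paste0(out2, "_process.csv")))
  j <- jsonlite::read_json(paste0(out2, "_test.json"))
  expect_gt(j$p, 0)
  expect_lte(j$p, 1)
  expect_error(scoredif_main(c("frobnicate")), class = "scoredif_cli_error")
  expect_error(scoredif_main(c("test")), class = "scoredif_cli_error")
})

test_that("the study driver is reproducible and tabulates rejections", {
  g <- study_grid(model = "2PL", n_persons = 150, n_items = 5,
                  covariate = "categorical", impact = FALSE,
                  dif = c("none", "intercept"), estimation = "MML",
                  engine = "pooled")
  expect_equal(nrow(g), 2L)
  r1 <- run_study(g, reps = 4, seed = 10)
  r2 <- run_study(g, reps = 4, seed = 10)
  expect_identical(r1, r2)
  # per-replicate streams make the result independent of the worker count
  r3 <- run_study(g, reps = 4, seed = 10, jobs = 2)
  expect_identical(r1, r3)
  expect_named(r1, c(names(g), "reps", "failures", "rejections", "rate",
                     "mc_se"))
  expect_true(all(r1$rate >= 0 & r1$rate <= 1, na.rm = TRUE))
  # guessing DIF rows are dropped under the 2PL
  g2 <- study_grid(model = "2PL", dif = "guessing")
  expect_equal(nrow(g2), 0L)
})
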