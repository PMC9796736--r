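# Delimited-text and JSON input/output.

#' Read and write response data
#'
#' Responses travel as headered CSV with one row per person: 0/1 item
#' columns (named `item1..itemJ` by convention) plus optional covariate and
#' group columns referenced by name.
#'
#' @param path File path.
#' @param items Optional item column names to validate; default: all columns
#'   whose name starts with `"item"`.
#' @return A tibble.
#' @export
read_responses <- function(path, items = NULL) {
  dat <- readr::read_csv(path, show_col_types = FALSE)
  items <- items %||% grep("^item", names(dat), value = TRUE)
  if (length(items) < 2) {
    rlang::abort("response file needs at least two item columns",
                 class = "scoredif_data_error")
  }
  vals <- unlist(dat[items], use.names = FALSE)
  if (anyNA(vals) || !all(vals %in% c(0, 1))) {
    rlang::abort("item columns must be complete and binary 0/1",
                 class = "scoredif_data_error")
  }
  dat
}

#' @rdname read_responses
#' @param data Data frame of responses.
#' @export
write_responses <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' Serialise fitted models and test results to JSON
#'
#' Fitted models carry the item and group parameters, the prior spec, the
#' quadrature and the convergence record; test results carry the statistic,
#' p-value, engine and the seed, giving a complete audit trail.
#'
#' @param fit An `irt_fit`.
#' @param path Output path.
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(
    model = fit$model, method = fit$method,
    items = as.data.frame(fit$params),
    group_params = as.data.frame(fit$group_params),
    prior = fit$prior,
    quadrature = list(n = fit$quad$n, range = range(fit$quad$x)),
    logLik = fit$loglik, logPost = fit$logpost,
    convergence = fit$convergence[c("em_iterations", "em_delta",
                                    "gradient_sup_norm")]
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit_json
#' @param test A `dif_test` or `test_result`.
#' @export
write_test_json <- function(test, path) {
  r <- if (inherits(test, "dif_test")) test$result else test
  obj <- list(statistic = r$statistic, value = r$value, p = r$p,
              engine = r$engine, R = r$R, seed = r$seed, k = r$k, N = r$N,
              m = r$m)
  jsonlite::write_json(obj[!vapply(obj, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit_json
#' @param process A `score_process`.
#' @export
write_process_csv <- function(process, path) {
  readr::write_csv(tidy.score_process(process), path)
  invisible(path)
}
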