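# Independent oracles used across the tests: dense-grid integration of the
# person-wise marginal likelihood and finite-difference gradients.  These
# deliberately avoid the package's quadrature/E-step code paths.

# trapezoid rule on a uniform grid
trapz <- function(x, y) {
  h <- x[2] - x[1]
  h * (sum(y) - (y[1] + y[length(y)]) / 2)
}

# marginal likelihood of one person's responses by dense-grid integration
# over theta ~ N(mean, var); params is a plain data frame with a, d, c
dense_person_loglik <- function(y, params, mean = 0, var = 1,
                                n_grid = 10001, range = c(-8, 8)) {
  th <- seq(range[1], range[2], length.out = n_grid)
  logf <- stats::dnorm(th, mean, sqrt(var), log = TRUE)
  for (j in seq_along(y)) {
    p <- params$c[j] + (1 - params$c[j]) *
      stats::plogis(params$a[j] * th + params$d[j])
    logf <- logf + if (y[j] == 1) log(p) else log1p(-p)
  }
  log(trapz(th, exp(logf)))
}

# central finite-difference gradient of f at x
fd_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h
    xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# finite-difference gradient of one person's dense-grid marginal
# log-likelihood with respect to the stacked item parameters
fd_person_score <- function(y, params, model, mean = 0, var = 1, h = 1e-6,
                            n_grid = 4001) {
  pars <- if (model == "2PL") c("a", "d") else c("a", "d", "c")
  x0 <- as.vector(t(as.matrix(params[pars])))
  f <- function(x) {
    m <- matrix(x, nrow = nrow(params), byrow = TRUE)
    p2 <- data.frame(a = m[, 1], d = m[, 2],
                     c = if (model == "3PL") m[, 3] else 0)
    dense_person_loglik(y, p2, mean, var, n_grid = n_grid)
  }
  fd_gradient(f, x0, h)
}

# simulate one decorrelated k-dimensional tied-down cumulative sum path
# (a discrete standard Brownian bridge) and return its (N+1) x k values
simulate_bridge_path <- function(N, k) {
  S <- matrix(stats::rnorm(N * k), N, k)
  S <- sweep(S, 2, colMeans(S))
  rbind(0, apply(S, 2, cumsum) / sqrt(N))
}

# build a score_process object directly from a score matrix (bypassing any
# model fitting), used for statistic-level tests
process_from_scores <- function(S, covariate, mode = "pooled",
                                groups = NULL) {
  sc <- structure(S, state = "raw", class = c("score_matrix", "matrix", "array"))
  cs <- center_scores(sc)
  V <- score_covariance(cs, mode = mode, groups = groups)
  build_process(cs, V, covariate, groups = groups)
}
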