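# Shared fixtures built in code.

# three-item calibration of the worked scoring example (logit metric)
demo_items <- function() worked_example_items()

# small random model instance for property-style tests
random_instance <- function(N, J, seed, D = 1.7) {
  set.seed(seed)
  items <- item_params(a = runif(J, 0.5, 2), b = rnorm(J), c = runif(J, 0, 0.25), D = D)
  theta <- rnorm(N)
  tstar <- matrix(rnorm(N * J, 1, 1), N, J)
  y <- matrix(rbinom(N * J, 1, 0.5), N, J)
  list(items = items, theta = theta, tstar = tstar, y = y)
}

# independent brute-force Bernoulli log-likelihood (naive double loop,
# scalar arithmetic only)
naive_loglik <- function(y, theta, items, tstar = NULL) {
  total <- 0
  for (i in seq_len(nrow(y))) {
    for (j in seq_len(ncol(y))) {
      denom <- 1 + exp(-items$D * items$a[j] * (theta[i] - items$b[j]))
      if (!is.null(tstar)) denom <- denom + exp(-tstar[i, j])
      p <- items$c[j] + (1 - items$c[j]) / denom
      total <- total + ifelse(y[i, j] == 1, log(p), log(1 - p))
    }
  }
  total
}

# grid-quadrature posterior for a single free discrimination parameter with
# everything else fixed (independent oracle for the sampler)
grid_posterior_a <- function(y, theta, b, c, tstar, D = 1.7,
                             grid = seq(0.01, 8, by = 0.002),
                             prior_meanlog = 0, prior_sdlog = 1) {
  logpost <- vapply(grid, function(a) {
    it <- item_params(a, b, c, D = D)
    loglik_g3plt(y, theta, it, tstar) + dlnorm(a, prior_meanlog, prior_sdlog, log = TRUE)
  }, numeric(1))
  w <- exp(logpost - max(logpost))
  w <- w / sum(w)
  list(grid = grid, w = w, mean = sum(grid * w),
       sd = sqrt(sum(grid^2 * w) - sum(grid * w)^2),
       quantile = function(p) grid[which.max(cumsum(w) >= p)])
}
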