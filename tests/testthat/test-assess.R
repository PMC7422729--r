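single_draw_fixture <- function(N = 3, J = 2, seed = 81) {
  set.seed(seed)
  list(draws = list(theta = matrix(rnorm(N), 1, N), a = matrix(runif(J, 0.5, 1.5), 1, J),
                    b = matrix(rnorm(J), 1, J), c = matrix(runif(J, 0, 0.2), 1, J)),
       y = matrix(rbinom(N * J, 1, 0.5), N, J),
       ts = matrix(rnorm(N * J, 1, 1), N, J))
}

test_that("a single draw gives pD = 0, DIC = its deviance, LPML = its log-likelihood", {
  fx <- single_draw_fixture()
  items <- item_params(fx$draws$a[1, ], fx$draws$b[1, ], fx$draws$c[1, ], D = 1.7)
  ll <- loglik_g3plt(fx$y, fx$draws$theta[1, ], items, fx$ts)
  res <- assess_fit(fx$draws, fx$y, fx$ts, D = 1.7)
  expect_equal(res$p_d, 0, tolerance = 1e-9)
  expect_equal(res$dic, -2 * ll, tolerance = 1e-8)
  expect_equal(res$lpml, ll, tolerance = 1e-8)
  expect_equal(sum(res$cpo_log), res$lpml, tolerance = 1e-9)
})

test_that("two listed draws match a spreadsheet-style hand computation", {
  # 3 persons x 2 items, two draws enumerated with scalar arithmetic
  y <- matrix(c(1L, 0L, 1L, 0L, 1L, 1L), 3, 2)
  ts <- matrix(c(0.2, 1.1, -0.4, 0.9, 0.3, 1.6), 3, 2)
  d1 <- list(theta = c(-0.5, 0.2, 1.0), a = c(1.0, 0.8), b = c(0.1, -0.3), c = c(0.1, 0.05))
  d2 <- list(theta = c(-0.2, 0.4, 0.8), a = c(1.2, 0.9), b = c(-0.1, 0.2), c = c(0.15, 0.02))
  pcell <- function(d, i, j)
    d$c[j] + (1 - d$c[j]) / (1 + exp(-1.7 * d$a[j] * (d$theta[i] - d$b[j])) + exp(-ts[i, j]))
  logf <- function(d) {
    out <- matrix(NA_real_, 3, 2)
    for (i in 1:3) for (j in 1:2) {
      p <- pcell(d, i, j)
      out[i, j] <- if (y[i, j] == 1) log(p) else log(1 - p)
    }
    out
  }
  lf1 <- logf(d1); lf2 <- logf(d2)
  dev_bar <- mean(c(-2 * sum(lf1), -2 * sum(lf2)))
  dmean <- list(theta = (d1$theta + d2$theta) / 2, a = (d1$a + d2$a) / 2,
                b = (d1$b + d2$b) / 2, c = (d1$c + d2$c) / 2)
  dev_hat <- -2 * sum(logf(dmean))
  p_d <- dev_bar - dev_hat
  lpml <- sum(log(2 / (exp(-lf1) + exp(-lf2))))  # per-cell harmonic mean of f
  draws <- list(theta = rbind(d1$theta, d2$theta), a = rbind(d1$a, d2$a),
                b = rbind(d1$b, d2$b), c = rbind(d1$c, d2$c))
  res <- assess_fit(draws, y, ts, D = 1.7)
  expect_equal(res$dev_bar, dev_bar, tolerance = 1e-10)
  expect_equal(res$dev_at_mean, dev_hat, tolerance = 1e-10)
  expect_equal(res$dic, dev_hat + 2 * p_d, tolerance = 1e-10)
  expect_equal(res$lpml, lpml, tolerance = 1e-10)
  # wrapper views agree with the joint pass
  expect_equal(compute_dic(draws, y, ts, D = 1.7)$dic, res$dic)
  expect_equal(compute_lpml(draws, y, ts, D = 1.7)$lpml, res$lpml)
})

test_that("two-draw CPO equals the closed-form harmonic mean on one cell", {
  y <- matrix(1L)
  ts <- matrix(0.5)
  draws <- list(theta = matrix(c(-1, 1)), a = matrix(c(1, 1.5)),
                b = matrix(c(0, 0.2)), c = matrix(c(0.1, 0.05)))
  p <- vapply(1:2, function(r)
    prob_g3plt(draws$theta[r, ], item_params(draws$a[r, ], draws$b[r, ],
                                             draws$c[r, ], D = 1.7), 0.5)[1, 1],
    numeric(1))
  res <- compute_lpml(draws, y, ts, D = 1.7)
  expect_equal(res$cpo_log[1, 1], log(2 / (1 / p[1] + 1 / p[2])), tolerance = 1e-12)
})

test_that("max-adjusted accumulation keeps extreme cells finite", {
  # a hopeless correct answer: log density near the clipping floor every draw
  y <- matrix(1L)
  ts <- matrix(-700)
  draws <- list(theta = matrix(rep(-30, 500)), a = matrix(rep(2, 500)),
                b = matrix(rep(5, 500)), c = matrix(rep(1e-9, 500)))
  res <- assess_fit(draws, y, ts, D = 1.7)
  expect_true(is.finite(res$lpml) && is.finite(res$dic))
  expect_lt(res$cpo_log[1, 1], -20)
})

test_that("LPML never exceeds the best draw's log-likelihood and ignores draw order", {
  for (seed in c(91, 92, 93)) {
    set.seed(seed)
    R <- 40; N <- 6; J <- 3
    draws <- list(theta = matrix(rnorm(R * N), R, N),
                  a = matrix(runif(R * J, 0.5, 2), R, J),
                  b = matrix(rnorm(R * J), R, J),
                  c = matrix(runif(R * J, 0, 0.3), R, J))
    y <- matrix(rbinom(N * J, 1, 0.5), N, J)
    ts <- matrix(rnorm(N * J, 1, 1), N, J)
    res <- assess_fit(draws, y, ts, D = 1.7)
    ll_draws <- vapply(1:R, function(r)
      loglik_g3plt(y, draws$theta[r, ],
                   item_params(draws$a[r, ], draws$b[r, ], draws$c[r, ], D = 1.7),
                   ts), numeric(1))
    expect_lte(res$lpml, max(ll_draws) + 1e-9)
    perm <- sample(R)
    shuffled <- lapply(draws, function(m) m[perm, , drop = FALSE])
    res2 <- assess_fit(shuffled, y, ts, D = 1.7)
    expect_equal(res2$dic, res$dic, tolerance = 1e-9)
    expect_equal(res2$lpml, res$lpml, tolerance = 1e-9)
  }
})

test_that("LPML converges to the quadrature leave-one-out predictive density", {
  # one free discrimination parameter: the exact posterior and the exact
  # conditional predictive ordinates are available by grid quadrature
  set.seed(95)
  N <- 20
  theta <- rnorm(N); b <- 0.2; cc <- 0.1
  it <- item_params(1.1, b, cc, D = 1.7)
  ts <- matrix(rnorm(N, 1, 0.8), N, 1)
  y <- sim_responses(theta, it, ts, W = 0, seed = 96)
  oracle <- grid_posterior_a(y, theta, b, cc, ts)
  f_cell <- function(a) {
    p <- prob_g3plt(theta, item_params(a, b, cc, D = 1.7), ts)
    ifelse(y == 1, p, 1 - p)
  }
  fmat <- vapply(oracle$grid, f_cell, matrix(numeric(1), N, 1))   # N x 1 x G
  inv_mean <- apply(fmat, 1, function(fr) sum(oracle$w / fr))
  lpml_quad <- sum(-log(inv_mean))
  fit <- fit_g3plt(y, ts, iter = 22000, burnin = 2000, chains = 1, seed = 97,
                   update = "a", init = list(theta = theta, a = 1, b = b, c = cc))
  res <- assess_fit(fit)
  expect_equal(res$lpml, lpml_quad, tolerance = 0.02)
})
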