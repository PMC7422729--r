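# Metropolis-Hastings within Gibbs estimation of (theta, a, b, c).
#
# The production sampler lives in C++ (src/sampler.cpp); the R-level
# mh_step_* functions implement the same four block updates one cycle at a
# time, using the identical random-number draw order, and exist so that the
# acceptance arithmetic can be checked against hand computation and prior
# sampling in tests and small experiments.

#' Prior configuration
#'
#' Defaults: `theta ~ N(0, 1)` (this is also the identification constraint on
#' the latent scale), `b ~ N(0, 1)`, `a ~ logN(0, 1)`, `c ~ Beta(2, 10)`.
#'
#' @param theta_mean,theta_sd normal prior on ability.
#' @param b_mean,b_sd normal prior on difficulty.
#' @param a_meanlog,a_sdlog lognormal prior on discrimination.
#' @param c_shape1,c_shape2 Beta prior on guessing.
#' @return list of class `"prior_config"`.
#' @export
prior_config <- function(theta_mean = 0, theta_sd = 1, b_mean = 0, b_sd = 1,
                         a_meanlog = 0, a_sdlog = 1, c_shape1 = 2,
                         c_shape2 = 10) {
  stopifnot(theta_sd > 0, b_sd > 0, a_sdlog > 0, c_shape1 > 0, c_shape2 > 0)
  structure(list(theta = c(theta_mean, theta_sd), b = c(b_mean, b_sd),
                 a = c(a_meanlog, a_sdlog), c = c(c_shape1, c_shape2)),
            class = "prior_config")
}

#' Proposal configuration
#'
#' Random-walk scales for the four blocks: normal walks for ability and
#' difficulty, a lognormal walk for discrimination, and a uniform window of
#' half-width `c_halfwidth` (default 0.01) for guessing. The normal/lognormal
#' scales are starting values; during burn-in they are tuned toward a 20-50%
#' block acceptance rate and then frozen.
#'
#' @param v_theta,v_b,v_a random-walk standard deviations.
#' @param c_halfwidth half-width of the uniform guessing proposal (not tuned).
#' @return list of class `"proposal_config"`.
#' @export
proposal_config <- function(v_theta = 1, v_b = 0.5, v_a = 0.3,
                            c_halfwidth = 0.01) {
  stopifnot(v_theta > 0, v_b > 0, v_a > 0, c_halfwidth > 0)
  structure(list(v_theta = v_theta, v_b = v_b, v_a = v_a,
                 c_halfwidth = c_halfwidth), class = "proposal_config")
}

# scalar/vector probability used by the R reference steps (same clipping as C++)
.pcell <- function(theta, a, b, c, D, tstar) {
  denom <- 1 + exp(.clip_exp(-D * a * (theta - b)))
  if (!is.null(tstar)) denom <- denom + exp(.clip_exp(-tstar))
  p <- c + (1 - c) / denom
  pmin(pmax(p, .P_EPS), 1 - .P_EPS)
}

.state_check <- function(state, data) {
  stopifnot(is.list(state), all(c("theta", "a", "b", "c") %in% names(state)),
            is.list(data), "y" %in% names(data))
  invisible(TRUE)
}

#' One Metropolis step for the ability block
#'
#' Proposes `theta* ~ N(theta_i, v_theta^2)` independently for each examinee
#' and accepts with the ratio of (row likelihood x normal prior) at the
#' proposed versus current value. The proposal is symmetric, so no Jacobian
#' term appears.
#'
#' @param state list with current `theta`, `a`, `b`, `c`.
#' @param data list with binary matrix `y`, optional `tstar` matrix (NULL for
#'   the plain 3PL), and scaling constant `D` (default 1.7).
#' @param priors a [prior_config()].
#' @param proposals a [proposal_config()].
#' @return the updated state, with an `accepted` logical attribute.
#' @export
mh_step_theta <- function(state, data, priors = prior_config(),
                          proposals = proposal_config()) {
  .state_check(state, data)
  D <- if (is.null(data$D)) 1.7 else data$D
  y <- data$y; tstar <- data$tstar
  N <- length(state$theta)
  prop <- rnorm(N, state$theta, proposals$v_theta)
  u <- runif(N)
  acc <- logical(N)
  for (i in seq_len(N)) {
    ts_i <- if (is.null(tstar)) NULL else tstar[i, ]
    ll <- function(th) {
      if (ncol(y) == 0) return(0)
      p <- .pcell(th, state$a, state$b, state$c, D, ts_i)
      sum(y[i, ] * log(p) + (1 - y[i, ]) * log(1 - p))
    }
    lr <- ll(prop[i]) - ll(state$theta[i]) +
      dnorm(prop[i], priors$theta[1], priors$theta[2], log = TRUE) -
      dnorm(state$theta[i], priors$theta[1], priors$theta[2], log = TRUE)
    if (log(u[i]) < lr) {
      state$theta[i] <- prop[i]
      acc[i] <- TRUE
    }
  }
  attr(state, "accepted") <- acc
  state
}

.col_ll <- function(y, tstar, D, j, theta, a_j, b_j, c_j) {
  if (nrow(y) == 0) return(0)
  ts_j <- if (is.null(tstar)) NULL else tstar[, j]
  p <- .pcell(theta, a_j, b_j, c_j, D, ts_j)
  sum(y[, j] * log(p) + (1 - y[, j]) * log(1 - p))
}

#' One Metropolis step for the difficulty block
#'
#' Mirror of [mh_step_theta()] over items: normal random walk on each `b_j`
#' with the column likelihood and the normal prior on difficulty.
#'
#' @inheritParams mh_step_theta
#' @return the updated state, with an `accepted` logical attribute.
#' @export
mh_step_b <- function(state, data, priors = prior_config(),
                      proposals = proposal_config()) {
  .state_check(state, data)
  D <- if (is.null(data$D)) 1.7 else data$D
  J <- length(state$b)
  prop <- rnorm(J, state$b, proposals$v_b)
  u <- runif(J)
  acc <- logical(J)
  for (j in seq_len(J)) {
    lr <- .col_ll(data$y, data$tstar, D, j, state$theta, state$a[j], prop[j], state$c[j]) -
      .col_ll(data$y, data$tstar, D, j, state$theta, state$a[j], state$b[j], state$c[j]) +
      dnorm(prop[j], priors$b[1], priors$b[2], log = TRUE) -
      dnorm(state$b[j], priors$b[1], priors$b[2], log = TRUE)
    if (log(u[j]) < lr) {
      state$b[j] <- prop[j]
      acc[j] <- TRUE
    }
  }
  attr(state, "accepted") <- acc
  state
}

#' One Metropolis step for the discrimination block
#'
#' Lognormal random walk `a* ~ logN(log a_j, v_a^2)`. The proposal is
#' asymmetric on the natural scale, so the acceptance ratio carries the
#' correction factor `a*/a_j` alongside the lognormal prior ratio; dropping it
#' (`jacobian = FALSE`, for diagnostics only) targets the wrong distribution.
#'
#' @inheritParams mh_step_theta
#' @param jacobian include the proposal-asymmetry factor (default TRUE; FALSE
#'   exists only to demonstrate the induced bias).
#' @return the updated state, with an `accepted` logical attribute.
#' @export
mh_step_a <- function(state, data, priors = prior_config(),
                      proposals = proposal_config(), jacobian = TRUE) {
  .state_check(state, data)
  D <- if (is.null(data$D)) 1.7 else data$D
  J <- length(state$a)
  prop <- exp(rnorm(J, log(state$a), proposals$v_a))
  u <- runif(J)
  acc <- logical(J)
  for (j in seq_len(J)) {
    lr <- .col_ll(data$y, data$tstar, D, j, state$theta, prop[j], state$b[j], state$c[j]) -
      .col_ll(data$y, data$tstar, D, j, state$theta, state$a[j], state$b[j], state$c[j]) +
      dlnorm(prop[j], priors$a[1], priors$a[2], log = TRUE) -
      dlnorm(state$a[j], priors$a[1], priors$a[2], log = TRUE)
    if (jacobian) lr <- lr + log(prop[j]) - log(state$a[j])
    if (log(u[j]) < lr) {
      state$a[j] <- prop[j]
      acc[j] <- TRUE
    }
  }
  attr(state, "accepted") <- acc
  state
}

#' One Metropolis step for the guessing block
#'
#' Uniform window proposal `c* ~ U(c_j - h, c_j + h)` with the Beta prior;
#' proposals outside `(0, 1)` have zero prior density and are rejected
#' outright.
#'
#' @inheritParams mh_step_theta
#' @return the updated state, with an `accepted` logical attribute.
#' @export
mh_step_c <- function(state, data, priors = prior_config(),
                      proposals = proposal_config()) {
  .state_check(state, data)
  D <- if (is.null(data$D)) 1.7 else data$D
  J <- length(state$c)
  h <- proposals$c_halfwidth
  prop <- runif(J, state$c - h, state$c + h)
  u <- runif(J)
  acc <- logical(J)
  for (j in seq_len(J)) {
    if (prop[j] <= 0 || prop[j] >= 1) next
    lr <- .col_ll(data$y, data$tstar, D, j, state$theta, state$a[j], state$b[j], prop[j]) -
      .col_ll(data$y, data$tstar, D, j, state$theta, state$a[j], state$b[j], state$c[j]) +
      dbeta(prop[j], priors$c[1], priors$c[2], log = TRUE) -
      dbeta(state$c[j], priors$c[1], priors$c[2], log = TRUE)
    if (log(u[j]) < lr) {
      state$c[j] <- prop[j]
      acc[j] <- TRUE
    }
  }
  attr(state, "accepted") <- acc
  state
}

# data-driven starting values: standardized person/item logits
.init_state <- function(y, priors) {
  N <- nrow(y); J <- ncol(y)
  th <- qlogis((rowSums(y) + 0.5) / (J + 1))
  th <- (th - mean(th)) / max(sd(th), 0.1)
  b0 <- -qlogis((colSums(y) + 0.5) / (N + 1))
  if (J > 1) b0 <- (b0 - mean(b0)) / max(sd(b0), 0.1)
  list(theta = th, a = rep(1, J), b = b0,
       c = rep(priors$c[1] / (priors$c[1] + priors$c[2]), J))
}

# overdispersed variant for chains beyond the first
.jitter_state <- function(state) {
  list(theta = state$theta + rnorm(length(state$theta), 0, 0.5),
       a = state$a * exp(rnorm(length(state$a), 0, 0.3)),
       b = state$b + rnorm(length(state$b), 0, 0.5),
       c = plogis(qlogis(state$c) + rnorm(length(state$c), 0, 0.3)))
}

#' Fit the model by Metropolis-Hastings within Gibbs
#'
#' Cycles the four block updates (ability, difficulty, discrimination,
#' guessing) per iteration, discards a burn-in, and keeps the remainder.
#' Multiple chains start from overdispersed (jittered) versions of a
#' data-driven initialization; the first chain starts unjittered. The latent
#' scale is identified through the standard-normal prior on ability; draws
#' are not rescaled afterwards.
#'
#' @param y N x J binary response matrix (1 = correct).
#' @param tstar N x J matrix of transformed times, a [transform_times()]
#'   result, or `NULL` to fit the plain 3PL.
#' @param W time weight added to `tstar` before fitting (ignored when
#'   `tstar` is `NULL`).
#' @param priors a [prior_config()].
#' @param proposals a [proposal_config()] of starting proposal scales.
#' @param iter total iterations per chain (default 10000).
#' @param burnin burn-in iterations discarded per chain (default 5000).
#' @param chains number of chains (default 4).
#' @param seed optional integer seed (applies to the whole run).
#' @param D logistic scaling constant.
#' @param tune tune proposal scales during burn-in (default TRUE).
#' @param update character subset of `c("theta", "b", "a", "c")` naming the
#'   blocks to sample; the rest stay fixed at their initial values (useful
#'   for conditional-posterior checks).
#' @param init optional list with starting `theta`, `a`, `b`, `c` (used for
#'   every chain, jittered for chains after the first).
#' @return object of class `"g3plt_fit"`: per-chain draw matrices, acceptance
#'   rates, tuned proposal scales, and the data/configuration needed by
#'   [assess_fit()] and [summary.g3plt_fit()].
#' @examples
#' d <- sim_g3plt_data(60, 4, W = 1, seed = 7)
#' fit <- fit_g3plt(d$y, d$tstar, W = 1, iter = 400, burnin = 200,
#'                  chains = 1, seed = 1)
#' head(summary(fit))
#' @export
fit_g3plt <- function(y, tstar = NULL, W = 0, priors = prior_config(),
                      proposals = proposal_config(), iter = 10000,
                      burnin = 5000, chains = 4, seed = NULL, D = 1.7,
                      tune = TRUE, update = c("theta", "b", "a", "c"),
                      init = NULL) {
  y <- .check_y(y)
  N <- nrow(y); J <- ncol(y)
  if (N < 1 || J < 1) stop("need at least one examinee and one item")
  if (burnin >= iter) stop("`burnin` must be smaller than `iter`")
  use_time <- !is.null(tstar)
  tmat <- if (use_time) .broadcast_tstar(tstar, N, J) + W else matrix(0, N, J)
  upd <- c("theta", "b", "a", "c") %in% update
  if (!any(upd)) stop("`update` selects no blocks")
  if (!is.null(seed)) set.seed(seed)

  base_init <- if (is.null(init)) .init_state(y, priors) else init
  stopifnot(length(base_init$theta) == N, length(base_init$a) == J)

  draws <- vector("list", chains)
  accept <- matrix(NA_real_, chains, 4,
                   dimnames = list(NULL, c("theta", "b", "a", "c")))
  prop_sd <- matrix(NA_real_, chains, 4)
  for (k in seq_len(chains)) {
    st <- if (k == 1) base_init else .jitter_state(base_init)
    res <- .sampler_cpp(y, tmat, use_time, D,
                        priors$theta, priors$b, priors$a, priors$c,
                        c(proposals$v_theta, proposals$v_b, proposals$v_a,
                          proposals$c_halfwidth),
                        st$theta, st$a, st$b, st$c, iter, burnin, tune, upd)
    draws[[k]] <- res[c("theta", "a", "b", "c")]
    accept[k, ] <- res$accept
    prop_sd[k, ] <- res$prop_sd
  }
  structure(list(draws = draws, accept = accept, prop_sd = prop_sd,
                 y = y, tstar = if (use_time) tmat else NULL,
                 use_time = use_time, D = D, N = N, J = J,
                 iter = iter, burnin = burnin, chains = chains,
                 priors = priors, seed = seed, update = update),
            class = "g3plt_fit")
}

#' @export
print.g3plt_fit <- function(x, ...) {
  cat(sprintf("G3PLT fit: %d examinees x %d items, %s\n", x$N, x$J,
              if (x$use_time) "time-modulated" else "plain 3PL"))
  cat(sprintf("%d chain(s) of %d iterations (%d burn-in)\n",
              x$chains, x$iter, x$burnin))
  cat("mean block acceptance rates:\n")
  print(round(colMeans(x$accept), 3))
  invisible(x)
}

#' Concatenate posterior draws across chains
#'
#' @param fit a [fit_g3plt()] object.
#' @param block one of `"theta"`, `"a"`, `"b"`, `"c"`.
#' @return matrix of draws (rows) by parameters (columns).
#' @export
posterior_draws <- function(fit, block = c("theta", "a", "b", "c")) {
  block <- match.arg(block)
  do.call(rbind, lapply(fit$draws, `[[`, block))
}

#' Shortest credible interval from posterior draws
#'
#' The highest-posterior-density interval is taken as the shortest interval
#' containing `prob` of the sorted draws.
#'
#' @param x numeric vector of draws.
#' @param prob target mass, default 0.95.
#' @return length-2 vector `c(lower, upper)`.
#' @export
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  k <- max(1, ceiling(prob * n))
  if (k >= n) return(c(x[1], x[n]))
  width <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(width)
  c(x[i], x[i + k])
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Standard between/within-chain variance ratio per scalar parameter. Values
#' below 1.2 are conventionally taken as converged.
#'
#' @param chains list (length >= 2) of draw matrices with equal dimensions,
#'   one per chain, parameters in columns; plain vectors are accepted for a
#'   single scalar parameter.
#' @return numeric vector of PSRF values, one per column.
#' @export
psrf <- function(chains) {
  chains <- lapply(chains, function(ch) if (is.matrix(ch)) ch else matrix(ch, ncol = 1))
  m <- length(chains)
  if (m < 2) stop("PSRF needs at least two chains")
  n <- nrow(chains[[1]])
  if (any(vapply(chains, nrow, 1L) != n)) stop("chains must have equal lengths")
  means <- sapply(chains, colMeans)
  vars <- sapply(chains, function(ch) apply(ch, 2, var))
  if (is.null(dim(means))) { means <- matrix(means, nrow = 1); vars <- matrix(vars, nrow = 1) }
  B <- n * apply(means, 1, var)
  Wv <- rowMeans(vars)
  vhat <- (n - 1) / n * Wv + (m + 1) / (m * n) * B
  sqrt(vhat / Wv)
}

#' Posterior summary table
#'
#' EAP (posterior mean), posterior SD, 95% HPD interval per parameter, and
#' the PSRF across chains when more than one chain was run.
#'
#' @param object a [fit_g3plt()] object.
#' @param prob HPD mass, default 0.95.
#' @param ... unused.
#' @return data.frame with columns `parameter`, `index`, `eap`, `sd`,
#'   `hpd_lower`, `hpd_upper`, and `psrf` (NA for single-chain fits).
#' @export
summary.g3plt_fit <- function(object, prob = 0.95, ...) {
  blocks <- c("theta", "a", "b", "c")
  out <- lapply(blocks, function(bl) {
    if (!(bl %in% object$update)) return(NULL)
    d <- posterior_draws(object, bl)
    hpd <- apply(d, 2, hpd_interval, prob = prob)
    rhat <- if (object$chains >= 2)
      psrf(lapply(object$draws, `[[`, bl)) else rep(NA_real_, ncol(d))
    data.frame(parameter = bl, index = seq_len(ncol(d)),
               eap = colMeans(d), sd = apply(d, 2, sd),
               hpd_lower = hpd[1, ], hpd_upper = hpd[2, ], psrf = rhat)
  })
  do.call(rbind, out)
}
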