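# Seeded simulators for item parameters, abilities, structured response
# times, and binary responses.

#' Simulate item parameters
#'
#' Discriminations from a normal with mean 1 and variance 0.2 truncated to the
#' positive half-line (by rejection), difficulties from N(0, 1), guessing
#' probabilities from Beta(2, 10) (mean 1/6).
#'
#' @param J number of items.
#' @param seed optional integer seed.
#' @param D logistic scaling constant stored in the result.
#' @return an [item_params()] object.
#' @export
sim_item_params <- function(J, seed = NULL, D = 1.7) {
  if (!is.null(seed)) set.seed(seed)
  if (J < 1) stop("J must be at least 1")
  a <- numeric(0)
  while (length(a) < J) {
    cand <- rnorm(J, 1, sqrt(0.2))
    a <- c(a, cand[cand > 0])
  }
  item_params(a = a[seq_len(J)], b = rnorm(J), c = rbeta(J, 2, 10), D = D)
}

#' Simulate abilities
#'
#' Abilities are standard normal, matching the identification constraint that
#' fixes the latent-trait mean and variance to 0 and 1.
#'
#' @param N number of examinees.
#' @param seed optional integer seed.
#' @return numeric vector of length N.
#' @export
sim_abilities <- function(N, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (N < 1) stop("N must be at least 1")
  rnorm(N)
}

#' Simulate structured transformed response times
#'
#' Emulates a design in which harder items take longer and abler examinees
#' answer faster:
#' \enumerate{
#'   \item item-level times are drawn log-normally, `log t_j ~ N(0.5, 0.25)`
#'     (variance), and standardized to `t*_j = (log t_j - 0.5)/0.5`, so
#'     `t*_j ~ N(0, 1)`;
#'   \item the sorted `t*_j` are assigned to items in ascending-difficulty
#'     order (easiest item gets the smallest item time);
#'   \item within each item, N person times are drawn from a normal with mean
#'     `t*_j` and variance 0.5, sorted, and assigned to examinees in
#'     descending-ability order (ablest examinee gets the smallest time).
#' }
#' The rank pairing is exact, so within every item the Spearman correlation
#' between ability and time is -1, and across items the correlation between
#' difficulty and the item-level time is +1.
#'
#' @param items an [item_params()] object (difficulties drive the pairing).
#' @param theta ability vector (length N).
#' @param seed optional integer seed.
#' @return N x J matrix of transformed times (no weight added), with the
#'   item-level centers attached as attribute `"tstar_item"`.
#' @export
sim_structured_times <- function(items, theta, seed = NULL) {
  items <- .check_items(items)
  if (!is.null(seed)) set.seed(seed)
  N <- length(theta); J <- items$J
  tstar_item <- (log(rlnorm(J, 0.5, 0.5)) - 0.5) / 0.5   # N(0,1) item times
  tstar_item <- sort(tstar_item)[rank(items$b, ties.method = "first")]
  tstar <- matrix(NA_real_, N, J)
  slow_to_fast <- order(theta, decreasing = TRUE)
  for (j in seq_len(J)) {
    tij <- sort(rnorm(N, tstar_item[j], sqrt(0.5)))
    tstar[slow_to_fast, j] <- tij
  }
  attr(tstar, "tstar_item") <- tstar_item
  tstar
}

#' Simulate binary responses
#'
#' Draws `Y_ij ~ Bernoulli(p_ij)` with `p_ij` from the time-modulated model
#' evaluated at `tstar + W`: the time weight enters additively on the
#' transformed-time scale, so data generated with weight `W` are exactly the
#' model fitted with the same weight.
#'
#' @param theta ability vector.
#' @param items an [item_params()] object.
#' @param tstar N x J matrix of transformed times (without the weight).
#' @param W time weight in `[0, 8]`.
#' @param seed optional integer seed.
#' @return N x J integer matrix of 0/1 responses (1 = correct).
#' @export
sim_responses <- function(theta, items, tstar, W = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (W < 0 || W > 8) stop("time weight `W` must lie in [0, 8]")
  p <- prob_g3plt(theta, items, tstar + W)
  y <- matrix(rbinom(length(p), 1, p), nrow(p), ncol(p))
  storage.mode(y) <- "integer"
  y
}

#' Simulate a complete dataset
#'
#' One replication of the full design: item parameters, abilities, structured
#' times, and responses, all from a single seed.
#'
#' @param N examinees.
#' @param J items.
#' @param W time weight used when generating responses.
#' @param seed optional integer seed.
#' @param D logistic scaling constant.
#' @return list with `items`, `theta`, `tstar` (weight not included), `y`,
#'   and `W`.
#' @examples
#' d <- sim_g3plt_data(50, 5, W = 1, seed = 1)
#' colMeans(d$y)
#' @export
sim_g3plt_data <- function(N, J, W = 1, seed = NULL, D = 1.7) {
  if (!is.null(seed)) set.seed(seed)
  items <- sim_item_params(J, D = D)
  theta <- sim_abilities(N)
  tstar <- sim_structured_times(items, theta)
  y <- sim_responses(theta, items, tstar, W = W)
  list(items = items, theta = theta, tstar = tstar, y = y, W = W)
}
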