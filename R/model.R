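# Probability kernel of the time-modulated 3PL model and its analytic limits.

.EXP_CLIP <- 700
.P_EPS <- 1e-12

.clip_exp <- function(x) pmin(pmax(x, -.EXP_CLIP), .EXP_CLIP)

#' Item parameter set
#'
#' Bundles per-item discrimination, difficulty, and guessing parameters with
#' the logistic scaling constant `D`.
#'
#' @param a numeric vector of discriminations, all positive.
#' @param b numeric vector of difficulties (ability scale).
#' @param c numeric vector of guessing probabilities in `[0, 1)`. Scalars are
#'   recycled to the length of `a`.
#' @param D logistic scaling constant, default 1.7 (the classical value that
#'   brings the logistic close to the normal ogive). Set `D = 1` for the logit
#'   metric.
#' @return An object of class `"item_params"`: a list with elements `a`, `b`,
#'   `c`, `D` and the item count `J`.
#' @examples
#' it <- item_params(a = c(0.8, 1, 1.2), b = c(-1, 0, 1), c = c(0, 0.05, 0.1))
#' prob_3pl(0, it)
#' @export
item_params <- function(a, b, c = 0, D = 1.7) {
  a <- as.numeric(a); b <- as.numeric(b)
  J <- length(a)
  if (length(b) != J) stop("`a` and `b` must have the same length")
  c <- rep_len(as.numeric(c), J)
  if (any(!is.finite(a)) || any(a <= 0)) stop("all discriminations `a` must be positive")
  if (any(!is.finite(c)) || any(c < 0) || any(c >= 1)) stop("guessing `c` must lie in [0, 1)")
  if (!is.numeric(D) || length(D) != 1 || D <= 0) stop("`D` must be a positive scalar")
  structure(list(a = a, b = b, c = c, D = D, J = J), class = "item_params")
}

#' @export
print.item_params <- function(x, ...) {
  cat(sprintf("Item parameters (%d items, D = %g)\n", x$J, x$D))
  print(data.frame(item = seq_len(x$J), a = x$a, b = x$b, c = x$c), row.names = FALSE)
  invisible(x)
}

.check_items <- function(items) {
  if (!inherits(items, "item_params")) stop("`items` must be an `item_params` object")
  items
}

#' Standardize raw response times
#'
#' Maps raw response times (minutes) to the transformed-time scale
#' `t* = (log t - mu) / sigma + W`: the pooled log times are standardized and
#' shifted by the test-level time weight `W`. Large `W` weakens the time
#' effect; at `W` around 8 the model is indistinguishable from the plain 3PL.
#'
#' @param raw numeric matrix (or vector) of strictly positive times, persons
#'   in rows and items in columns.
#' @param mu location of the log times; `"auto"` (default) uses the pooled
#'   mean of `log(raw)`.
#' @param sigma scale of the log times; `"auto"` uses the pooled standard
#'   deviation of `log(raw)`.
#' @param W time weight in `[0, 8]`.
#' @return A list of class `"time_transform"` with the transformed matrix
#'   `tstar` and the metadata `mu`, `sigma`, `W` needed to reproduce it.
#' @examples
#' tt <- transform_times(matrix(rlnorm(12, 0.5, 0.5), 3, 4), W = 1)
#' tt$mu
#' @export
transform_times <- function(raw, mu = "auto", sigma = "auto", W = 0) {
  raw <- as.matrix(raw)
  if (!is.numeric(W) || length(W) != 1 || W < 0 || W > 8)
    stop("time weight `W` must be a scalar in [0, 8]")
  bad <- which(!is.finite(raw) | raw <= 0)
  if (length(bad)) {
    ij <- arrayInd(bad[1], dim(raw))
    stop(sprintf("response times must be positive and finite; offending cell [%d, %d]",
                 ij[1], ij[2]))
  }
  lt <- log(raw)
  if (identical(mu, "auto")) mu <- mean(lt)
  if (identical(sigma, "auto")) sigma <- sd(as.vector(lt))
  if (!is.finite(sigma) || sigma <= 0)
    stop("log-time scale `sigma` must be positive (times are constant?)")
  tstar <- (lt - mu) / sigma + W
  structure(list(tstar = tstar, mu = mu, sigma = sigma, W = W),
            class = "time_transform")
}

.broadcast_tstar <- function(tstar, N, J) {
  if (inherits(tstar, "time_transform")) tstar <- tstar$tstar
  if (is.null(tstar)) return(NULL)
  if (length(tstar) == 1) return(matrix(tstar, N, J))
  if (is.matrix(tstar)) {
    if (nrow(tstar) != N || ncol(tstar) != J)
      stop(sprintf("`tstar` must be %d x %d", N, J))
    return(tstar)
  }
  if (length(tstar) == J) return(matrix(tstar, N, J, byrow = TRUE))
  stop("`tstar` must be a scalar, a length-J vector, or an N x J matrix")
}

#' Correct-response probability under the time-modulated model
#'
#' Computes `p = c + (1 - c) / (1 + exp(-D a (theta - b)) + exp(-t*))`,
#' vectorized over persons (rows) and items (columns). The probability is
#' strictly increasing in both ability and transformed time; as `t*` grows the
#' 3PL probability is recovered, and as `t*` falls the probability drops to
#' the guessing floor `c`.
#'
#' @param theta numeric vector of abilities (length N).
#' @param items an [item_params()] object.
#' @param tstar transformed times: scalar, length-J vector, N x J matrix, or a
#'   [transform_times()] result.
#' @return N x J matrix of probabilities.
#' @examples
#' it <- item_params(1, 0, 0, D = 1.7)
#' prob_g3plt(0, it, tstar = 0)  # 1/3: the time term adds a third unit
#' @export
prob_g3plt <- function(theta, items, tstar) {
  items <- .check_items(items)
  theta <- as.numeric(theta)
  N <- length(theta); J <- items$J
  tstar <- .broadcast_tstar(tstar, N, J)
  if (is.null(tstar)) stop("`tstar` is required; use `prob_3pl()` for the plain 3PL")
  eta <- items$D * (outer(theta, items$a) -
                      matrix(items$a * items$b, N, J, byrow = TRUE))
  denom <- 1 + exp(.clip_exp(-eta)) + exp(.clip_exp(-tstar))
  cm <- matrix(items$c, N, J, byrow = TRUE)
  cm + (1 - cm) / denom
}

#' Correct-response probability under the plain 3PL model
#'
#' The large-`t*` limit of [prob_g3plt()]:
#' `p = c + (1 - c) / (1 + exp(-D a (theta - b)))`.
#'
#' @inheritParams prob_g3plt
#' @return N x J matrix of probabilities.
#' @export
prob_3pl <- function(theta, items) {
  items <- .check_items(items)
  theta <- as.numeric(theta)
  N <- length(theta); J <- items$J
  eta <- items$D * (outer(theta, items$a) -
                      matrix(items$a * items$b, N, J, byrow = TRUE))
  cm <- matrix(items$c, N, J, byrow = TRUE)
  cm + (1 - cm) / (1 + exp(.clip_exp(-eta)))
}

#' Ability at which a target 3PL probability is reached
#'
#' Inverts the 3PL response curve: `theta = b - log((1 - p)/(p - c)) / (D a)`.
#' This is the ability floor needed to reach probability `p` no matter how
#' much time is available (the vertical asymptote of the equiprobability
#' curve).
#'
#' @param items an [item_params()] object with a single item (or vectors are
#'   recycled elementwise).
#' @param p target probability, must satisfy `c < p < 1`.
#' @return numeric vector of abilities.
#' @export
ability_from_prob <- function(items, p) {
  items <- .check_items(items)
  if (any(p <= items$c) || any(p >= 1))
    stop("`p` must satisfy c < p < 1 (asymptote bounds)")
  items$b - log((1 - p) / (p - items$c)) / (items$D * items$a)
}

#' Transformed time at which a target probability is reached
#'
#' Inverts the large-ability limit of the response curve:
#' `t* = -log((1 - p)/(p - c))`. This is the time floor needed to reach
#' probability `p` no matter how able the examinee (the horizontal asymptote
#' of the equiprobability curve).
#'
#' @inheritParams ability_from_prob
#' @return numeric vector of transformed times.
#' @examples
#' tstar_from_prob(item_params(1.5, 1, 0.1), 0.5)  # -log(1.25), about -0.22
#' @export
tstar_from_prob <- function(items, p) {
  items <- .check_items(items)
  if (any(p <= items$c) || any(p >= 1))
    stop("`p` must satisfy c < p < 1 (asymptote bounds)")
  -log((1 - p) / (p - items$c))
}

.check_y <- function(y, J = NULL) {
  y <- as.matrix(y)
  if (any(is.na(y)) || !all(y %in% c(0, 1)))
    stop("responses must be 0/1 with no missing cells (1 = correct)")
  if (!is.null(J) && ncol(y) != J) stop("response matrix and item set disagree on J")
  storage.mode(y) <- "integer"
  y
}

#' Bernoulli log-likelihood of a response matrix
#'
#' Sums `y log p + (1 - y) log(1 - p)` over all person-item cells, with `p`
#' from [prob_g3plt()] when transformed times are supplied and from
#' [prob_3pl()] otherwise. Probabilities are clipped away from 0 and 1 before
#' logging so the result is always finite.
#'
#' @param y N x J binary response matrix, 1 = correct.
#' @param theta numeric vector of abilities (length N).
#' @param items an [item_params()] object.
#' @param tstar transformed times (scalar, vector, or matrix), or `NULL` for
#'   the plain 3PL likelihood.
#' @return scalar log-likelihood.
#' @export
loglik_g3plt <- function(y, theta, items, tstar = NULL) {
  items <- .check_items(items)
  y <- .check_y(y, items$J)
  if (nrow(y) != length(theta)) stop("response matrix and `theta` disagree on N")
  p <- if (is.null(tstar)) prob_3pl(theta, items) else prob_g3plt(theta, items, tstar)
  p <- pmin(pmax(p, .P_EPS), 1 - .P_EPS)
  sum(y * log(p) + (1 - y) * log(1 - p))
}
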