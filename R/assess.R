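# Bayesian model assessment from MCMC output: DIC and LPML.

.as_draws <- function(draws, y, tstar, D) {
  if (inherits(draws, "g3plt_fit")) {
    list(theta = posterior_draws(draws, "theta"), a = posterior_draws(draws, "a"),
         b = posterior_draws(draws, "b"), c = posterior_draws(draws, "c"),
         y = draws$y, tstar = draws$tstar, use_time = draws$use_time,
         D = draws$D)
  } else {
    stopifnot(is.list(draws), all(c("theta", "a", "b", "c") %in% names(draws)))
    if (is.null(y)) stop("`y` is required when `draws` is a plain draw list")
    y <- .check_y(y)
    use_time <- !is.null(tstar)
    list(theta = as.matrix(draws$theta), a = as.matrix(draws$a),
         b = as.matrix(draws$b), c = as.matrix(draws$c), y = y,
         tstar = if (use_time) .broadcast_tstar(tstar, nrow(y), ncol(y)),
         use_time = use_time, D = D)
  }
}

#' Joint Bayesian assessment of a fitted model
#'
#' One pass over the posterior draws computing both goodness-of-fit
#' statistics: the deviance information criterion
#' `DIC = Dev(mean) + 2 pD` with `pD = mean(Dev) - Dev(mean)` (the deviance
#' at the posterior-mean parameters, all on their natural scales), and the
#' log pseudomarginal likelihood `LPML = sum log CPO_ij`, where each
#' conditional predictive ordinate is the harmonic mean of the cell's
#' per-draw densities, evaluated with a max-value adjustment so that cells
#' with extreme negative log densities stay finite. Smaller DIC and larger
#' LPML indicate better fit.
#'
#' @param draws a [fit_g3plt()] object (data are taken from it), or a list
#'   with draw matrices `theta` (R x N), `a`, `b`, `c` (R x J).
#' @param y binary response matrix; only needed for a plain draw list.
#' @param tstar transformed-time matrix (weight already included), or `NULL`
#'   for the 3PL likelihood; only used for a plain draw list.
#' @param D logistic scaling constant; only used for a plain draw list.
#' @return list of class `"g3plt_assessment"` with `dic`, `p_d`, `dev_bar`,
#'   `dev_at_mean`, `lpml`, and the N x J matrix `cpo_log`.
#' @export
assess_fit <- function(draws, y = NULL, tstar = NULL, D = 1.7) {
  dd <- .as_draws(draws, y, tstar, D)
  if (nrow(dd$theta) < 1) stop("need at least one retained draw")
  tmat <- if (dd$use_time) dd$tstar else matrix(0, nrow(dd$y), ncol(dd$y))
  res <- .assess_cpp(dd$theta, dd$a, dd$b, dd$c, dd$y, tmat, dd$use_time, dd$D)
  structure(list(dic = res$dev_at_mean + 2 * (res$dev_bar - res$dev_at_mean),
                 p_d = res$dev_bar - res$dev_at_mean,
                 dev_bar = res$dev_bar, dev_at_mean = res$dev_at_mean,
                 lpml = res$lpml, cpo_log = res$cpo_log),
            class = "g3plt_assessment")
}

#' @export
print.g3plt_assessment <- function(x, ...) {
  cat(sprintf("DIC = %.3f (pD = %.3f), LPML = %.3f\n", x$dic, x$p_d, x$lpml))
  invisible(x)
}

#' Deviance information criterion
#'
#' @inheritParams assess_fit
#' @return list with `dic`, `p_d`, `dev_bar`, `dev_at_mean`.
#' @seealso [assess_fit()] for both statistics in one pass.
#' @export
compute_dic <- function(draws, y = NULL, tstar = NULL, D = 1.7) {
  r <- assess_fit(draws, y, tstar, D)
  r[c("dic", "p_d", "dev_bar", "dev_at_mean")]
}

#' Log pseudomarginal likelihood
#'
#' @inheritParams assess_fit
#' @return list with `lpml` and the per-cell matrix `cpo_log`.
#' @seealso [assess_fit()] for both statistics in one pass.
#' @export
compute_lpml <- function(draws, y = NULL, tstar = NULL, D = 1.7) {
  r <- assess_fit(draws, y, tstar, D)
  r[c("lpml", "cpo_log")]
}
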