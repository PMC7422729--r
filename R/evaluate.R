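# Replication-level accuracy indices for simulation studies.

#' Parameter-recovery metrics over replications
#'
#' Given `M` replications of posterior estimates for `P` parameters with
#' known truths, computes per parameter:
#' bias `mean(est - truth)`, MSE `mean((est - truth)^2)`, simulation SE (the
#' square root of the `1/M`-normalized sample variance of the estimates),
#' the average posterior SD, and the coverage probability of the 95% HPD
#' intervals. When a `class` grouping is supplied (e.g. discrimination /
#' difficulty / guessing), per-class averages of each metric are returned as
#' well.
#'
#' @param estimates M x P matrix of point estimates (e.g. EAPs).
#' @param post_sds M x P matrix of posterior SDs (optional, NA allowed).
#' @param hpd_lower,hpd_upper M x P matrices of interval endpoints
#'   (optional).
#' @param truth length-P vector of true values.
#' @param class optional length-P grouping for class averages.
#' @return list of class `"recovery_report"` with `per_parameter` and
#'   (when `class` is given) `by_class` data.frames, and `M`.
#' @examples
#' est <- rbind(c(1.1, 0.2), c(0.9, -0.2))
#' recovery_metrics(est, truth = c(1, 0))$per_parameter
#' @export
recovery_metrics <- function(estimates, post_sds = NULL, hpd_lower = NULL,
                             hpd_upper = NULL, truth, class = NULL) {
  estimates <- as.matrix(estimates)
  M <- nrow(estimates); P <- ncol(estimates)
  if (length(truth) != P) stop("`truth` must have one value per parameter")
  chk <- function(m) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    if (!all(dim(m) == c(M, P))) stop("metric matrices must all be M x P")
    m
  }
  post_sds <- chk(post_sds); hpd_lower <- chk(hpd_lower); hpd_upper <- chk(hpd_upper)

  tm <- matrix(truth, M, P, byrow = TRUE)
  bias <- colMeans(estimates - tm)
  mse <- colMeans((estimates - tm)^2)
  ctr <- sweep(estimates, 2, colMeans(estimates))
  sim_se <- sqrt(colMeans(ctr^2))          # 1/M normalization
  avg_sd <- if (is.null(post_sds)) rep(NA_real_, P) else colMeans(post_sds)
  cp <- if (is.null(hpd_lower) || is.null(hpd_upper)) rep(NA_real_, P)
        else colMeans(hpd_lower <= tm & tm <= hpd_upper)

  per <- data.frame(parameter = if (is.null(colnames(estimates)))
                      paste0("p", seq_len(P)) else colnames(estimates),
                    truth = truth, bias = bias, mse = mse, sim_se = sim_se,
                    avg_sd = avg_sd, cp = cp, row.names = NULL)
  out <- list(per_parameter = per, M = M)
  if (!is.null(class)) {
    if (length(class) != P) stop("`class` must have one label per parameter")
    agg <- aggregate(per[c("bias", "mse", "sim_se", "avg_sd", "cp")],
                     by = list(class = class), FUN = mean)
    out$by_class <- agg
  }
  structure(out, class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Recovery over %d replications\n", x$M))
  if (!is.null(x$by_class)) print(x$by_class, row.names = FALSE)
  else print(head(x$per_parameter), row.names = FALSE)
  invisible(x)
}

#' @importFrom stats aggregate
#' @importFrom utils head
NULL
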