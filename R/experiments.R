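# Scripted study reproductions: the worked ability-comparison table, the
# parameter-recovery study, and the model-comparison study.

#' Item calibration of the worked scoring example
#'
#' The three-item calibration used by [ability_comparison_table()]:
#' discriminations 0.8/1/1.2, difficulties -1/0/1, guessing 0/0.05/0.1. The
#' reference ability estimates for this example reproduce under the logit
#' metric, so `D = 1` here.
#'
#' @return an [item_params()] object with three items and `D = 1`.
#' @export
worked_example_items <- function() {
  item_params(a = c(0.8, 1, 1.2), b = c(-1, 0, 1), c = c(0, 0.05, 0.1), D = 1)
}

#' Ability estimates across time intensities for fixed response patterns
#'
#' Scores each response framework under the time-modulated model at every
#' value of a shared scalar transformed time, and under the plain 3PL, by
#' maximum likelihood. The table isolates what response time adds: patterns
#' produced faster (smaller `t*`) are credited with more ability, and at
#' `t* = 8` the two models agree to within optimizer precision.
#'
#' @param items an [item_params()] object; defaults to
#'   [worked_example_items()].
#' @param frameworks list of 0/1 response vectors (1 = correct).
#' @param tstar_grid scalar transformed times applied to all items.
#' @return data.frame with columns `model` ("G3PLT"/"3PL"), `framework`,
#'   `tstar` (NA for the 3PL rows), and `theta`.
#' @examples
#' tab <- ability_comparison_table()
#' subset(tab, model == "3PL")
#' @export
ability_comparison_table <- function(items = worked_example_items(),
                                     frameworks = list(c(1, 0, 0), c(0, 1, 0),
                                                       c(1, 1, 0)),
                                     tstar_grid = c(-0.2, 0, 0.2, 0.5, 1, 2, 3, 8)) {
  fw_lab <- vapply(frameworks, function(y)
    paste0("(", paste(y, collapse = ", "), ")"), character(1))
  rows <- list()
  for (f in seq_along(frameworks)) {
    prof <- ability_profile(frameworks[[f]], items, tstar_grid)
    rows[[length(rows) + 1]] <- data.frame(model = "G3PLT",
                                           framework = fw_lab[f],
                                           tstar = prof$tstar,
                                           theta = prof$theta)
    ml3 <- estimate_ability(frameworks[[f]], items, tstar = NULL)
    rows[[length(rows) + 1]] <- data.frame(model = "3PL", framework = fw_lab[f],
                                           tstar = NA_real_, theta = ml3$theta)
  }
  do.call(rbind, rows)
}

#' Parameter-recovery study
#'
#' For each replication: simulate a dataset ([sim_g3plt_data()] with fixed
#' item/ability truths shared across replications), fit the matched model by
#' MCMC, and summarize the item-parameter posteriors. Recovery metrics
#' (bias, MSE, simulation SE, average posterior SD, 95% HPD coverage) are
#' returned per parameter and averaged within the discrimination /
#' difficulty / guessing classes.
#'
#' Truths are drawn once per study from the generating distributions; the
#' `reps` replications then redraw the response times and responses.
#'
#' @param N examinees.
#' @param J items.
#' @param W time weight used in generation and fitting.
#' @param reps replications (the study's M).
#' @param iter,burnin,chains MCMC settings per fit.
#' @param seed integer seed for the whole study.
#' @param D logistic scaling constant.
#' @param progress print one line per replication.
#' @return list with the `recovery_report` (`report`), the truths, and the
#'   per-replication PSRF maxima (`psrf_max`, NA for single-chain fits).
#' @export
run_recovery_study <- function(N = 500, J = 20, W = 1, reps = 20,
                               iter = 3000, burnin = 1500, chains = 1,
                               seed = 1, D = 1.7, progress = FALSE) {
  set.seed(seed)
  items <- sim_item_params(J, D = D)
  theta <- sim_abilities(N)
  P <- 3 * J
  est <- sds <- lo <- hi <- matrix(NA_real_, reps, P)
  psrf_max <- rep(NA_real_, reps)
  for (m in seq_len(reps)) {
    # per-replication reseed: data depend only on (seed, m), not on how much
    # RNG the previous fits consumed
    set.seed((seed + m) %% .Machine$integer.max)
    tstar <- sim_structured_times(items, theta)
    y <- sim_responses(theta, items, tstar, W = W)
    fit <- fit_g3plt(y, tstar, W = W, iter = iter, burnin = burnin,
                     chains = chains, D = D)
    sm <- summary(fit)
    it <- sm[sm$parameter %in% c("a", "b", "c"), ]
    it <- it[order(match(it$parameter, c("a", "b", "c")), it$index), ]
    est[m, ] <- it$eap; sds[m, ] <- it$sd
    lo[m, ] <- it$hpd_lower; hi[m, ] <- it$hpd_upper
    if (chains >= 2) psrf_max[m] <- max(sm$psrf, na.rm = TRUE)
    if (progress) message(sprintf("replication %d/%d done", m, reps))
  }
  truth <- c(items$a, items$b, items$c)
  cls <- rep(c("discrimination", "difficulty", "guessing"), each = J)
  colnames(est) <- paste0(cls, "_", rep(seq_len(J), 3))
  report <- recovery_metrics(est, sds, lo, hi, truth, class = cls)
  list(report = report, items = items, theta = theta, psrf_max = psrf_max,
       design = list(N = N, J = J, W = W, reps = reps, iter = iter,
                     burnin = burnin, chains = chains, seed = seed))
}

#' Model-comparison study
#'
#' For each replication of data generated with a true time weight, fits both
#' the plain 3PL and the time-modulated model with the matched weight, and
#' assesses both by DIC and LPML. Reports quartiles (Q1/median/Q3/IQR) of
#' each statistic per fitted model and the fraction of replications in which
#' the matched model wins (smaller DIC, larger LPML).
#'
#' @param W_true true time weight used in generation.
#' @param N examinees.
#' @param J items.
#' @param reps replications.
#' @param iter,burnin,chains MCMC settings per fit.
#' @param seed integer seed.
#' @param D logistic scaling constant.
#' @param progress print one line per replication.
#' @return list with `quartiles` (data.frame: model, statistic, Q1, median,
#'   Q3, IQR), `wins` (named fractions for DIC and LPML), and the raw
#'   per-replication values.
#' @export
run_model_comparison_study <- function(W_true = 0, N = 1000, J = 20,
                                       reps = 20, iter = 3000, burnin = 1500,
                                       chains = 1, seed = 1, D = 1.7,
                                       progress = FALSE) {
  set.seed(seed)
  items <- sim_item_params(J, D = D)
  theta <- sim_abilities(N)
  vals <- data.frame(rep = integer(0), model = character(0),
                     dic = numeric(0), lpml = numeric(0))
  for (m in seq_len(reps)) {
    set.seed((seed + m) %% .Machine$integer.max)
    tstar <- sim_structured_times(items, theta)
    y <- sim_responses(theta, items, tstar, W = W_true)
    fit_g <- fit_g3plt(y, tstar, W = W_true, iter = iter, burnin = burnin,
                       chains = chains, D = D)
    fit_3 <- fit_g3plt(y, tstar = NULL, iter = iter, burnin = burnin,
                       chains = chains, D = D)
    as_g <- assess_fit(fit_g); as_3 <- assess_fit(fit_3)
    vals <- rbind(vals,
                  data.frame(rep = m, model = "G3PLT", dic = as_g$dic, lpml = as_g$lpml),
                  data.frame(rep = m, model = "3PL", dic = as_3$dic, lpml = as_3$lpml))
    if (progress) message(sprintf("replication %d/%d done", m, reps))
  }
  qline <- function(x) {
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    c(Q1 = q[1], median = q[2], Q3 = q[3], IQR = q[3] - q[1])
  }
  quart <- do.call(rbind, lapply(c("3PL", "G3PLT"), function(md) {
    v <- vals[vals$model == md, ]
    rbind(data.frame(model = md, statistic = "DIC", t(qline(v$dic))),
          data.frame(model = md, statistic = "LPML", t(qline(v$lpml))))
  }))
  g <- vals[vals$model == "G3PLT", ]; p3 <- vals[vals$model == "3PL", ]
  wins <- c(dic = mean(g$dic < p3$dic), lpml = mean(g$lpml > p3$lpml))
  list(quartiles = quart, wins = wins, values = vals,
       design = list(W_true = W_true, N = N, J = J, reps = reps, iter = iter,
                     burnin = burnin, chains = chains, seed = seed))
}
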