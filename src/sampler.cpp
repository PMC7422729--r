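// Metropolis-Hastings within Gibbs sampler for the time-modulated 3PL model,
// plus a one-pass deviance / CPO accumulator over posterior draws.
//
// All random numbers come from R's RNG so runs are reproducible from
// set.seed(), and the draw order within each block (all proposals, then all
// acceptance uniforms) matches the R reference step functions exactly.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double EXP_CLIP = 700.0;
static const double P_EPS = 1e-12;

static inline double clip_exp(double x) {
  if (x > EXP_CLIP) return EXP_CLIP;
  if (x < -EXP_CLIP) return -EXP_CLIP;
  return x;
}

static inline double cell_prob(double theta, double a, double b, double c,
                               double D, double tstar, bool use_time) {
  double denom = 1.0 + std::exp(clip_exp(-D * a * (theta - b)));
  if (use_time) denom += std::exp(clip_exp(-tstar));
  return c + (1.0 - c) / denom;
}

static inline double cell_logf(int y, double p) {
  if (p < P_EPS) p = P_EPS;
  if (p > 1.0 - P_EPS) p = 1.0 - P_EPS;
  return y ? std::log(p) : std::log(1.0 - p);
}

// log-likelihood of person i's row
static double row_loglik(const IntegerMatrix& y, const NumericMatrix& tstar,
                         bool use_time, double D, int i, double theta,
                         const NumericVector& a, const NumericVector& b,
                         const NumericVector& c) {
  long double s = 0.0;
  const int J = y.ncol();
  for (int j = 0; j < J; ++j) {
    double p = cell_prob(theta, a[j], b[j], c[j], D,
                         use_time ? tstar(i, j) : 0.0, use_time);
    s += cell_logf(y(i, j), p);
  }
  return (double)s;
}

// log-likelihood of item j's column
static double col_loglik(const IntegerMatrix& y, const NumericMatrix& tstar,
                         bool use_time, double D, int j,
                         const NumericVector& theta, double a, double b,
                         double c) {
  long double s = 0.0;
  const int N = y.nrow();
  for (int i = 0; i < N; ++i) {
    double p = cell_prob(theta[i], a, b, c, D,
                         use_time ? tstar(i, j) : 0.0, use_time);
    s += cell_logf(y(i, j), p);
  }
  return (double)s;
}

// [[Rcpp::export(name = ".sampler_cpp")]]
List sampler_cpp(IntegerMatrix y, NumericMatrix tstar, bool use_time, double D,
                 NumericVector prior_theta,  // mean, sd
                 NumericVector prior_b,      // mean, sd
                 NumericVector prior_a,      // meanlog, sdlog
                 NumericVector prior_c,      // shape1, shape2
                 NumericVector prop,         // v_theta, v_b, v_a, c_halfwidth
                 NumericVector theta0, NumericVector a0, NumericVector b0,
                 NumericVector c0, int iter, int burnin, bool tune,
                 LogicalVector update) {
  const int N = y.nrow(), J = y.ncol();
  const int kept = iter - burnin;
  if (kept < 1) stop("burn-in must be smaller than the iteration count");

  NumericVector theta = clone(theta0), a = clone(a0), b = clone(b0),
                cc = clone(c0);
  double v_theta = prop[0], v_b = prop[1], v_a = prop[2], c_half = prop[3];

  NumericMatrix th_draws(kept, N), a_draws(kept, J), b_draws(kept, J),
                c_draws(kept, J);
  // acceptance bookkeeping: post-burn-in totals and tuning-window totals
  double acc[4] = {0, 0, 0, 0};
  double win[4] = {0, 0, 0, 0};
  const int win_len = 100;

  NumericVector prop_v(N > J ? N : J), u(N > J ? N : J);

  for (int r = 0; r < iter; ++r) {
    bool keep = r >= burnin;

    if (update[0]) {  // ability block
      for (int i = 0; i < N; ++i) prop_v[i] = R::rnorm(theta[i], v_theta);
      for (int i = 0; i < N; ++i) u[i] = R::unif_rand();
      for (int i = 0; i < N; ++i) {
        double lr = row_loglik(y, tstar, use_time, D, i, prop_v[i], a, b, cc) -
                    row_loglik(y, tstar, use_time, D, i, theta[i], a, b, cc) +
                    R::dnorm(prop_v[i], prior_theta[0], prior_theta[1], 1) -
                    R::dnorm(theta[i], prior_theta[0], prior_theta[1], 1);
        if (std::log(u[i]) < lr) {
          theta[i] = prop_v[i];
          if (keep) acc[0] += 1.0; else win[0] += 1.0;
        }
      }
    }

    if (update[1]) {  // difficulty block
      for (int j = 0; j < J; ++j) prop_v[j] = R::rnorm(b[j], v_b);
      for (int j = 0; j < J; ++j) u[j] = R::unif_rand();
      for (int j = 0; j < J; ++j) {
        double lr = col_loglik(y, tstar, use_time, D, j, theta, a[j], prop_v[j], cc[j]) -
                    col_loglik(y, tstar, use_time, D, j, theta, a[j], b[j], cc[j]) +
                    R::dnorm(prop_v[j], prior_b[0], prior_b[1], 1) -
                    R::dnorm(b[j], prior_b[0], prior_b[1], 1);
        if (std::log(u[j]) < lr) {
          b[j] = prop_v[j];
          if (keep) acc[1] += 1.0; else win[1] += 1.0;
        }
      }
    }

    if (update[2]) {  // discrimination block: lognormal random walk
      for (int j = 0; j < J; ++j) prop_v[j] = std::exp(R::rnorm(std::log(a[j]), v_a));
      for (int j = 0; j < J; ++j) u[j] = R::unif_rand();
      for (int j = 0; j < J; ++j) {
        // asymmetric proposal: q ratio contributes the factor a*/a
        double lr = col_loglik(y, tstar, use_time, D, j, theta, prop_v[j], b[j], cc[j]) -
                    col_loglik(y, tstar, use_time, D, j, theta, a[j], b[j], cc[j]) +
                    R::dlnorm(prop_v[j], prior_a[0], prior_a[1], 1) -
                    R::dlnorm(a[j], prior_a[0], prior_a[1], 1) +
                    std::log(prop_v[j]) - std::log(a[j]);
        if (std::log(u[j]) < lr) {
          a[j] = prop_v[j];
          if (keep) acc[2] += 1.0; else win[2] += 1.0;
        }
      }
    }

    if (update[3]) {  // guessing block: uniform window, zero prior outside (0,1)
      for (int j = 0; j < J; ++j) prop_v[j] = R::runif(cc[j] - c_half, cc[j] + c_half);
      for (int j = 0; j < J; ++j) u[j] = R::unif_rand();
      for (int j = 0; j < J; ++j) {
        if (prop_v[j] <= 0.0 || prop_v[j] >= 1.0) continue;
        double lr = col_loglik(y, tstar, use_time, D, j, theta, a[j], b[j], prop_v[j]) -
                    col_loglik(y, tstar, use_time, D, j, theta, a[j], b[j], cc[j]) +
                    R::dbeta(prop_v[j], prior_c[0], prior_c[1], 1) -
                    R::dbeta(cc[j], prior_c[0], prior_c[1], 1);
        if (std::log(u[j]) < lr) {
          cc[j] = prop_v[j];
          if (keep) acc[3] += 1.0; else win[3] += 1.0;
        }
      }
    }

    // proposal-scale tuning during burn-in only (frozen afterwards so the
    // retained draws come from a fixed kernel)
    if (tune && !keep && (r + 1) % win_len == 0) {
      double denom_np[4] = {(double)N, (double)J, (double)J, (double)J};
      double* vs[3] = {&v_theta, &v_b, &v_a};
      for (int k = 0; k < 3; ++k) {
        if (!update[k]) continue;
        double rate = win[k] / (win_len * denom_np[k]);
        if (rate < 0.2) *vs[k] *= std::exp(-0.25);
        else if (rate > 0.5) *vs[k] *= std::exp(0.25);
        win[k] = 0.0;
      }
      win[3] = 0.0;  // c half-width stays at its fixed value
    }

    if (keep) {
      int rr = r - burnin;
      for (int i = 0; i < N; ++i) th_draws(rr, i) = theta[i];
      for (int j = 0; j < J; ++j) {
        a_draws(rr, j) = a[j];
        b_draws(rr, j) = b[j];
        c_draws(rr, j) = cc[j];
      }
    }
  }

  NumericVector acc_rate = NumericVector::create(
      acc[0] / ((double)kept * N), acc[1] / ((double)kept * J),
      acc[2] / ((double)kept * J), acc[3] / ((double)kept * J));
  acc_rate.attr("names") = CharacterVector::create("theta", "b", "a", "c");
  NumericVector prop_out = NumericVector::create(v_theta, v_b, v_a, c_half);
  prop_out.attr("names") = CharacterVector::create("v_theta", "v_b", "v_a", "c_halfwidth");

  return List::create(_["theta"] = th_draws, _["a"] = a_draws,
                      _["b"] = b_draws, _["c"] = c_draws,
                      _["accept"] = acc_rate, _["prop_sd"] = prop_out);
}

// One pass over posterior draws accumulating, per cell, an online
// max-adjusted log-sum-exp of the negative log densities (for the CPO
// harmonic-mean estimator) and, globally, the mean deviance and the deviance
// at the posterior-mean parameters. Extended precision keeps the N*J sums
// stable.
// [[Rcpp::export(name = ".assess_cpp")]]
List assess_cpp(NumericMatrix theta_d, NumericMatrix a_d, NumericMatrix b_d,
                NumericMatrix c_d, IntegerMatrix y, NumericMatrix tstar,
                bool use_time, double D) {
  const int R = theta_d.nrow(), N = y.nrow(), J = y.ncol();
  if (R < 1) stop("need at least one retained draw");

  NumericMatrix mx(N, J);   // running max of -logf
  NumericMatrix sx(N, J);   // running sum of exp(-logf - mx)
  std::fill(mx.begin(), mx.end(), R_NegInf);
  long double dev_sum = 0.0;
  std::vector<long double> th_bar(N, 0.0), a_bar(J, 0.0), b_bar(J, 0.0),
      c_bar(J, 0.0);

  for (int r = 0; r < R; ++r) {
    long double ll = 0.0;
    for (int j = 0; j < J; ++j) {
      double aj = a_d(r, j), bj = b_d(r, j), cj = c_d(r, j);
      for (int i = 0; i < N; ++i) {
        double p = cell_prob(theta_d(r, i), aj, bj, cj, D,
                             use_time ? tstar(i, j) : 0.0, use_time);
        double lf = cell_logf(y(i, j), p);
        ll += lf;
        double x = -lf;
        if (x > mx(i, j)) {
          sx(i, j) = sx(i, j) * std::exp(mx(i, j) - x) + 1.0;
          mx(i, j) = x;
        } else {
          sx(i, j) += std::exp(x - mx(i, j));
        }
      }
    }
    dev_sum += -2.0L * ll;
    for (int i = 0; i < N; ++i) th_bar[i] += theta_d(r, i);
    for (int j = 0; j < J; ++j) {
      a_bar[j] += a_d(r, j);
      b_bar[j] += b_d(r, j);
      c_bar[j] += c_d(r, j);
    }
  }

  // deviance at the posterior mean (natural-scale means for all blocks)
  long double ll_hat = 0.0;
  for (int j = 0; j < J; ++j) {
    double aj = (double)(a_bar[j] / R), bj = (double)(b_bar[j] / R),
           cj = (double)(c_bar[j] / R);
    for (int i = 0; i < N; ++i) {
      double p = cell_prob((double)(th_bar[i] / R), aj, bj, cj, D,
                           use_time ? tstar(i, j) : 0.0, use_time);
      ll_hat += cell_logf(y(i, j), p);
    }
  }

  // log CPO_ij = log R - logsumexp_r(-logf_ij^(r))
  NumericMatrix logcpo(N, J);
  long double lpml = 0.0;
  const double logR = std::log((double)R);
  for (int j = 0; j < J; ++j)
    for (int i = 0; i < N; ++i) {
      double v = logR - (mx(i, j) + std::log(sx(i, j)));
      logcpo(i, j) = v;
      lpml += v;
    }

  return List::create(_["dev_bar"] = (double)(dev_sum / R),
                      _["dev_at_mean"] = (double)(-2.0L * ll_hat),
                      _["lpml"] = (double)lpml, _["cpo_log"] = logcpo);
}
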