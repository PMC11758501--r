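// Adaptive component-wise random-walk Metropolis for the Bayesian logistic
// dose-toxicity model with optional covariate coefficients under flat
// normal, Bayesian-LASSO (Laplace with InvGamma hyperprior on the rate per
// covariate group) or spike-and-slab covariate priors.
//
// Parameter vector layout: [alpha, log_beta, gamma_1..p, aux_1..a] where the
// auxiliaries are log(lambda_g) per LASSO group or logit(m_j) per
// spike-and-slab covariate.  Sampling uses R's RNG stream so results are
// reproducible via set.seed() on the R side.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Prior {
  int type;  // 0 none, 1 normal, 2 lasso, 3 spikeslab
  double m1, m2, p11, p12, p22;  // BVN mean and precision entries
  NumericVector sigma2;          // normal: per-coefficient variance
  IntegerVector group;           // lasso: 0-based group per covariate
  NumericVector group_delta;     // lasso: InvGamma(delta, delta) per group
  double b1, b2, slab_var;       // spike-and-slab
  NumericVector spike_var;
  bool swap;                     // put (1 - m_j) on the slab instead
};

const double PEPS = 1e-12;

double log_post(const NumericVector& th, int p, int G, const Prior& pr,
                const IntegerVector& y, const NumericVector& lr,
                const NumericMatrix& X) {
  const double alpha = th[0], lb = th[1];
  const double beta = std::exp(lb);
  double z1 = alpha - pr.m1, z2 = lb - pr.m2;
  double lp = -0.5 * (pr.p11 * z1 * z1 + 2.0 * pr.p12 * z1 * z2 +
                      pr.p22 * z2 * z2);
  if (pr.type == 1) {
    for (int j = 0; j < p; ++j) {
      double g = th[2 + j];
      lp += -0.5 * g * g / pr.sigma2[j];
    }
  } else if (pr.type == 2) {
    for (int g = 0; g < G; ++g) {
      double u = th[2 + p + g], lam = std::exp(u), d = pr.group_delta[g];
      // InvGamma(d, d) density in lambda plus the log-scale Jacobian
      lp += d * std::log(d) - lgamma(d) - (d + 1.0) * u - d / lam + u;
    }
    for (int j = 0; j < p; ++j) {
      double lam = std::exp(th[2 + p + pr.group[j]]);
      lp += std::log(lam / 2.0) - lam * std::fabs(th[2 + j]);
    }
  } else if (pr.type == 3) {
    for (int j = 0; j < p; ++j) {
      double zt = th[2 + p + j];
      double m = 1.0 / (1.0 + std::exp(-zt));
      double w_spike = pr.swap ? m : 1.0 - m;
      double g = th[2 + j];
      double dens =
          w_spike * R::dnorm(g, 0.0, std::sqrt(pr.spike_var[j]), 0) +
          (1.0 - w_spike) * R::dnorm(g, 0.0, std::sqrt(pr.slab_var), 0);
      lp += std::log(dens);
      // Beta(b1, b2) on m plus the logit-scale Jacobian m(1 - m)
      lp += R::dbeta(m, pr.b1, pr.b2, 1) + std::log(m) + std::log1p(-m);
    }
  }
  const int n = y.size();
  for (int i = 0; i < n; ++i) {
    double eta = alpha + beta * lr[i];
    for (int j = 0; j < p; ++j) eta += th[2 + j] * X(i, j);
    double pi = 1.0 / (1.0 + std::exp(-eta));
    if (pi < PEPS) pi = PEPS;
    if (pi > 1.0 - PEPS) pi = 1.0 - PEPS;
    lp += y[i] ? std::log(pi) : std::log1p(-pi);
  }
  return lp;
}

}  // namespace

// [[Rcpp::export]]
List blrm_mcmc_cpp(IntegerVector y, NumericVector lr, NumericMatrix X,
                   List prior, int n_chains, int warmup, int iter,
                   NumericMatrix init, double init_step) {
  const int p = X.ncol();
  Prior pr;
  pr.type = as<int>(prior["type"]);
  NumericVector m = prior["mean"];
  NumericMatrix P = prior["prec"];
  pr.m1 = m[0]; pr.m2 = m[1];
  pr.p11 = P(0, 0); pr.p12 = P(0, 1); pr.p22 = P(1, 1);
  pr.sigma2 = prior.containsElementNamed("sigma2")
                  ? as<NumericVector>(prior["sigma2"]) : NumericVector(0);
  pr.group = prior.containsElementNamed("group")
                 ? as<IntegerVector>(prior["group"]) : IntegerVector(0);
  pr.group_delta = prior.containsElementNamed("group_delta")
                       ? as<NumericVector>(prior["group_delta"])
                       : NumericVector(0);
  pr.b1 = prior.containsElementNamed("b1") ? as<double>(prior["b1"]) : 1.0;
  pr.b2 = prior.containsElementNamed("b2") ? as<double>(prior["b2"]) : 1.0;
  pr.slab_var = prior.containsElementNamed("slab_var")
                    ? as<double>(prior["slab_var"]) : 1.0;
  pr.spike_var = prior.containsElementNamed("spike_var")
                     ? as<NumericVector>(prior["spike_var"])
                     : NumericVector(0);
  pr.swap = prior.containsElementNamed("swap")
                ? as<bool>(prior["swap"]) : false;
  const int G = pr.group_delta.size();
  const int dim = 2 + p + (pr.type == 2 ? G : (pr.type == 3 ? p : 0));
  if (init.ncol() != dim || init.nrow() != n_chains)
    stop("init must be n_chains x dim");

  NumericMatrix draws(n_chains * iter, dim);
  IntegerVector chain_id(n_chains * iter);
  NumericVector acc_rate(dim);
  long long acc_count = 0, prop_count = 0;

  RNGScope scope;
  for (int c = 0; c < n_chains; ++c) {
    NumericVector th(dim);
    for (int j = 0; j < dim; ++j) th[j] = init(c, j);
    NumericVector ls(dim, std::log(init_step));
    double cur = log_post(th, p, G, pr, y, lr, X);
    IntegerVector batch_acc(dim);
    int batch_n = 0, batch_idx = 0;
    const int total = warmup + iter;
    for (int it = 0; it < total; ++it) {
      for (int j = 0; j < dim; ++j) {
        double old = th[j];
        th[j] = old + std::exp(ls[j]) * R::norm_rand();
        double cand = log_post(th, p, G, pr, y, lr, X);
        if (std::log(R::unif_rand()) < cand - cur) {
          cur = cand;
          ++batch_acc[j];
          if (it >= warmup) ++acc_count;
        } else {
          th[j] = old;
        }
        if (it >= warmup) ++prop_count;
      }
      ++batch_n;
      if (it < warmup && batch_n == 50) {  // Robbins-Monro style scaling
        ++batch_idx;
        double step = std::min(0.25, 1.0 / std::sqrt((double)batch_idx));
        for (int j = 0; j < dim; ++j) {
          double r = batch_acc[j] / 50.0;
          ls[j] += (r > 0.44 ? step : -step);
          batch_acc[j] = 0;
        }
        batch_n = 0;
      }
      if (it >= warmup) {
        int row = c * iter + (it - warmup);
        for (int j = 0; j < dim; ++j) draws(row, j) = th[j];
        chain_id[row] = c + 1;
      }
    }
  }
  return List::create(_["draws"] = draws, _["chain"] = chain_id,
                      _["accept_rate"] =
                          prop_count ? (double)acc_count / prop_count : NA_REAL);
}
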