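#include <Rcpp.h>
using namespace Rcpp;

// MCMC for one spatial transcriptomics spot under the model
//
//   y_i | h, beta0, sigma, nu  ~  t(nu, beta0 + W_i h, sigma)      i = 1..m
//   h ~ Dirichlet(alpha)  on the open p-simplex
//   nu = 3 + nu',  nu' ~ Gamma(shape 2, rate 0.1)
//   beta0 flat;  sigma ~ half-Cauchy(0, sigma_scale)
//   optionally, an extra Beta(tau*lam, (1-tau)*lam) log-density on
//   h_a = sum(h[prior_group]) (the image-derived prior factor).
//
// The simplex is parameterised through independent Gamma variates,
// h_k = g_k / sum(g); sampling is deterministic-scan slice sampling
// (Neal 2003, stepping out + shrinkage) on log g_k, beta0, log sigma
// and log nu'. (h, sum(g)) are independent under this construction, so
// a prior factor depending only on h leaves the marginal of h equal to
// Dirichlet(alpha) times that factor.

namespace {

struct SpotModel {
  const NumericVector y;
  const NumericMatrix W;
  const NumericVector alpha;
  const std::vector<int> group;  // 0-based columns of W under the Beta prior
  const double tau, lam;
  const bool has_prior;
  const double sigma_scale;
  const int m, p;

  // state
  std::vector<double> u;  // log g
  double beta0, ls, lv;   // log sigma, log nu'

  // cache: Wg_i = sum_k W(i,k) g_k, S = sum g
  std::vector<double> Wg;
  double S;

  SpotModel(NumericVector y_, NumericMatrix W_, NumericVector alpha_,
            IntegerVector group_, double tau_, double lam_,
            double sigma_scale_, double init_sigma)
      : y(y_), W(W_), alpha(alpha_),
        group(group_.begin(), group_.end()), tau(tau_), lam(lam_),
        has_prior(group_.size() > 0), sigma_scale(sigma_scale_),
        m(W_.nrow()), p(W_.ncol()),
        u(p, 0.0), beta0(0.0), ls(std::log(init_sigma)),
        lv(std::log(20.0)), Wg(m, 0.0), S(0.0) {
    refresh_cache();
  }

  void refresh_cache() {
    S = 0.0;
    for (int k = 0; k < p; ++k) S += std::exp(u[k]);
    for (int i = 0; i < m; ++i) {
      double acc = 0.0;
      for (int k = 0; k < p; ++k) acc += W(i, k) * std::exp(u[k]);
      Wg[i] = acc;
    }
  }

  // Student-t log-likelihood for given caches; dgk/kk: perturbation of
  // one gamma coordinate (kk < 0 means none).
  double loglik(double b0, double sigma, double nu, int kk, double dgk) const {
    const double Sx = S + (kk >= 0 ? dgk : 0.0);
    const double cst = R::lgammafn(0.5 * (nu + 1.0)) - R::lgammafn(0.5 * nu)
                     - 0.5 * std::log(nu * M_PI) - std::log(sigma);
    const double half = 0.5 * (nu + 1.0);
    const double inv_S = 1.0 / Sx, inv_sig = 1.0 / sigma, inv_nu = 1.0 / nu;
    const double* yp = y.begin();
    const double* wgp = Wg.data();
    double acc = 0.0;
    if (kk >= 0) {
      const double* wk = &W(0, kk);
      for (int i = 0; i < m; ++i) {
        double z = (yp[i] - b0 - (wgp[i] + wk[i] * dgk) * inv_S) * inv_sig;
        acc += std::log1p(z * z * inv_nu);
      }
    } else {
      for (int i = 0; i < m; ++i) {
        double z = (yp[i] - b0 - wgp[i] * inv_S) * inv_sig;
        acc += std::log1p(z * z * inv_nu);
      }
    }
    return m * cst - half * acc;
  }

  double log_prior_g(int k, double uk) const {
    return alpha[k] * uk - std::exp(uk);  // Gamma(alpha_k,1) + log-Jacobian
  }

  // Beta prior factor on h_a = sum(g[group]) / S, unnormalised
  double log_beta_factor(int kk, double dgk) const {
    if (!has_prior) return 0.0;
    double Sx = S + (kk >= 0 ? dgk : 0.0);
    double ga = 0.0;
    for (size_t t = 0; t < group.size(); ++t) {
      int k = group[t];
      ga += std::exp(u[k]) + (kk >= 0 && k == kk ? dgk : 0.0);
    }
    double ha = ga / Sx;
    if (ha <= 0.0 || ha >= 1.0) return R_NegInf;
    return (tau * lam - 1.0) * std::log(ha)
         + ((1.0 - tau) * lam - 1.0) * std::log1p(-ha);
  }

  // full conditionals (up to constants) -------------------------------
  double target_g(int k, double uk) const {
    double dgk = std::exp(uk) - std::exp(u[k]);
    double sigma = std::exp(ls), nu = 3.0 + std::exp(lv);
    return loglik(beta0, sigma, nu, k, dgk) + log_prior_g(k, uk)
         + log_beta_factor(k, dgk);
  }
  double target_beta0(double b0) const {
    return loglik(b0, std::exp(ls), 3.0 + std::exp(lv), -1, 0.0);
  }
  double target_ls(double ls_) const {
    double sigma = std::exp(ls_);
    double r = sigma / sigma_scale;
    return loglik(beta0, sigma, 3.0 + std::exp(lv), -1, 0.0)
         - std::log1p(r * r) + ls_;  // half-Cauchy + log-Jacobian
  }
  double target_lv(double lv_) const {
    double nu = 3.0 + std::exp(lv_);
    return loglik(beta0, std::exp(ls), nu, -1, 0.0)
         + 2.0 * lv_ - 0.1 * std::exp(lv_);  // Gamma(2, 0.1) + Jacobian
  }
};

// Univariate slice sampler, stepping out + shrinkage (Neal 2003).
template <class F>
double slice_update(double x0, F logf, double w, int max_steps) {
  double f0 = logf(x0);
  if (!R_finite(f0)) return x0;  // degenerate start: leave untouched
  double logy = f0 + std::log(R::unif_rand());
  double L = x0 - w * R::unif_rand();
  double Rr = L + w;
  int jl = std::floor(max_steps * R::unif_rand());
  int jr = max_steps - 1 - jl;
  while (jl-- > 0 && logf(L) > logy) L -= w;
  while (jr-- > 0 && logf(Rr) > logy) Rr += w;
  for (int it = 0; it < 1000; ++it) {
    double x1 = L + (Rr - L) * R::unif_rand();
    if (logf(x1) > logy) return x1;
    if (x1 < x0) L = x1; else Rr = x1;
  }
  return x0;
}

}  // namespace

// [[Rcpp::export(name = ".gist_spot_mcmc")]]
List gist_spot_mcmc(NumericVector y, NumericMatrix W, NumericVector alpha,
                    IntegerVector prior_group, double tau, double lam,
                    int iterations, int burn_in, double sigma_scale,
                    double init_sigma) {
  if (W.nrow() != y.size()) stop("W and y have incompatible dimensions");
  if (alpha.size() != W.ncol()) stop("alpha must have one entry per cell type");
  SpotModel mod(y, W, alpha, prior_group, tau, lam, sigma_scale, init_sigma);

  const int keep = iterations - burn_in;
  NumericMatrix h_draws(keep, mod.p);
  NumericVector nu_draws(keep), beta0_draws(keep), sigma_draws(keep);

  const double w_g = 1.0, w_sc = 0.7;
  const int max_steps = 50;

  for (int it = 0; it < iterations; ++it) {
    for (int k = 0; k < mod.p; ++k) {
      double uk = slice_update(
          mod.u[k], [&](double x) { return mod.target_g(k, x); }, w_g,
          max_steps);
      if (uk != mod.u[k]) {
        double dg = std::exp(uk) - std::exp(mod.u[k]);
        for (int i = 0; i < mod.m; ++i) mod.Wg[i] += mod.W(i, k) * dg;
        mod.S += dg;
        mod.u[k] = uk;
      }
    }
    // periodic exact refresh against drift of the incremental cache
    if ((it & 255) == 255) mod.refresh_cache();

    mod.beta0 = slice_update(
        mod.beta0, [&](double x) { return mod.target_beta0(x); }, w_sc,
        max_steps);
    mod.ls = slice_update(
        mod.ls, [&](double x) { return mod.target_ls(x); }, w_sc, max_steps);
    mod.lv = slice_update(
        mod.lv, [&](double x) { return mod.target_lv(x); }, w_sc, max_steps);

    if (it >= burn_in) {
      int r = it - burn_in;
      for (int k = 0; k < mod.p; ++k)
        h_draws(r, k) = std::exp(mod.u[k]) / mod.S;
      nu_draws[r] = 3.0 + std::exp(mod.lv);
      beta0_draws[r] = mod.beta0;
      sigma_draws[r] = std::exp(mod.ls);
    }
  }

  return List::create(_["h"] = h_draws, _["nu"] = nu_draws,
                      _["beta0"] = beta0_draws, _["sigma"] = sigma_draws);
}
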