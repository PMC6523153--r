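#include <Rcpp.h>
using namespace Rcpp;

// Weighted BayesB Gibbs sampler.
//
// Model: y_i = mu + sum_j Z_ij u_j + e_i,  e_i ~ N(0, sigma_e2 / w_i).
// Each locus effect u_j is a point-mass mixture: u_j = 0 with prior
// probability pi, else u_j ~ N(0, sigma_u2_j) with a locus-specific variance
// under a scaled inverse chi-square prior (nu, S2_u). delta_j and u_j are
// sampled jointly per locus by integrating u_j out analytically, which keeps
// the chain irreducible. Z must be column-centered; zero-variance columns
// (zwz == 0) are never updated and keep delta = 0.
//
// Uses R's RNG: call set.seed() in R before invoking for determinism.
// [[Rcpp::export]]
List bayesb_chain_cpp(NumericMatrix Z, NumericVector y, NumericVector w,
                      double pi_prior, int n_iter, int burn_in, int thin,
                      double nu, double S2_u, double nu_e, double S2_e,
                      double init_sigma_e2, bool fix_variances,
                      double fixed_sigma_u2, bool save_effects) {
  const int n = Z.nrow(), m = Z.ncol();
  if (n_iter <= burn_in) stop("n_iter must exceed burn_in");
  for (int i = 0; i < n; ++i)
    if (!R_finite(y[i]) || !R_finite(w[i]) || w[i] <= 0.0)
      stop("non-finite response or non-positive weight");

  // precompute weighted cross-products
  std::vector<double> zwz(m);
  NumericMatrix Zw(n, m); // w_i * Z_ij
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) {
      Zw(i, j) = w[i] * Z(i, j);
      s += Zw(i, j) * Z(i, j);
    }
    zwz[j] = s;
  }
  double wsum = 0.0;
  for (int i = 0; i < n; ++i) wsum += w[i];

  std::vector<double> u(m, 0.0), sigma_u2(m, fix_variances ? fixed_sigma_u2 : S2_u);
  std::vector<int> delta(m, 0);
  double mu = 0.0, sigma_e2 = init_sigma_e2;
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i];

  const int n_saved = (n_iter - burn_in) / thin;
  NumericVector u_sum(m), freq(m);
  NumericMatrix u_save;
  if (save_effects) u_save = NumericMatrix(n_saved, m);
  NumericVector sigma_e2_save(n_saved), mu_save(n_saved);

  int saved = 0;
  for (int it = 1; it <= n_iter; ++it) {
    // population mean
    double num = 0.0;
    for (int i = 0; i < n; ++i) num += w[i] * (e[i] + mu);
    double mu_new = num / wsum + ::norm_rand() * std::sqrt(sigma_e2 / wsum);
    for (int i = 0; i < n; ++i) e[i] += mu - mu_new;
    mu = mu_new;

    // loci: joint (delta_j, u_j) update
    for (int j = 0; j < m; ++j) {
      if (zwz[j] <= 0.0) continue;
      double su2 = fix_variances ? fixed_sigma_u2 : sigma_u2[j];
      double rhs = 0.0;
      const double uj_old = u[j];
      for (int i = 0; i < n; ++i) rhs += Zw(i, j) * e[i];
      rhs += uj_old * zwz[j];
      const double v1 = zwz[j] / sigma_e2;
      const double r1 = rhs / sigma_e2;
      const double post_var = 1.0 / (v1 + 1.0 / su2);
      const double post_mean = r1 * post_var;
      // log Bayes factor for inclusion (delta=1 vs 0), u integrated out
      double logbf = 0.5 * std::log(post_var / su2) +
                     0.5 * post_mean * post_mean / post_var;
      double p1;
      if (pi_prior <= 0.0) p1 = 1.0;
      else if (pi_prior >= 1.0) p1 = 0.0;
      else if (logbf > 700.0) p1 = 1.0;
      else {
        const double odds = (1.0 - pi_prior) / pi_prior * std::exp(logbf);
        p1 = odds / (1.0 + odds);
      }
      double uj_new = 0.0;
      int dj = (::unif_rand() < p1) ? 1 : 0;
      if (dj == 1)
        uj_new = post_mean + ::norm_rand() * std::sqrt(post_var);
      const double du = uj_new - uj_old;
      if (du != 0.0)
        for (int i = 0; i < n; ++i) e[i] -= Z(i, j) * du;
      u[j] = uj_new;
      delta[j] = dj;
    }

    if (!fix_variances) {
      // locus variances: scaled inv-chi2(nu + delta_j, ...)
      for (int j = 0; j < m; ++j) {
        if (zwz[j] <= 0.0) continue;
        if (delta[j] == 1)
          sigma_u2[j] = (nu * S2_u + u[j] * u[j]) / R::rchisq(nu + 1.0);
        else
          sigma_u2[j] = nu * S2_u / R::rchisq(nu);
      }
      // residual variance from weighted SSE
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += w[i] * e[i] * e[i];
      sigma_e2 = (sse + nu_e * S2_e) / R::rchisq((double)n + nu_e);
    }

    if (it > burn_in && (it - burn_in) % thin == 0 && saved < n_saved) {
      for (int j = 0; j < m; ++j) {
        u_sum[j] += u[j];
        freq[j] += delta[j];
        if (save_effects) u_save(saved, j) = u[j];
      }
      sigma_e2_save[saved] = sigma_e2;
      mu_save[saved] = mu;
      ++saved;
    }
    if (it % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  for (int j = 0; j < m; ++j) {
    u_sum[j] /= n_saved;
    freq[j] /= n_saved;
  }
  List out = List::create(
      _["post_mean_effect"] = u_sum, _["model_freq"] = freq,
      _["sigma_e2_samples"] = sigma_e2_save, _["mu_samples"] = mu_save,
      _["n_saved"] = n_saved);
  if (save_effects) out["u_samples"] = u_save;
  return out;
}
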