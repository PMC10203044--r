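#include <Rcpp.h>
using namespace Rcpp;

// Point-normal Gibbs sampler for one LD block, on the standardized
// (correlation) scale. Prior per SNP: spike at zero with probability
// 1 - p, slab N(0, s2). Marginal effects r have sampling variance 1/n and
// expectation R beta. Posterior means are Rao-Blackwellised: the average
// over post-burn-in sweeps of p_j * mu_j, the conditional inclusion
// probability times the conditional slab mean given the current values of
// the other SNPs. Update order is fixed (genome order) for
// reproducibility; R's RNG is used so set.seed() controls the draws.

// [[Rcpp::export]]
List gibbs_block_cpp(NumericMatrix R, NumericVector r, double n,
                     double s2, double p, int n_iter, int burn_in) {
  int b = r.size();
  NumericVector beta(b), Rbeta(b), postmean(b), pip(b);
  double tau2 = 1.0 / (n + 1.0 / s2);
  double v_slab = s2 + 1.0 / n, v_null = 1.0 / n;
  bool always_in = (p >= 1.0);
  double log_prior_odds = always_in ? 0.0 : std::log(p) - std::log1p(-p);
  int kept = 0;
  for (int it = 0; it < n_iter; ++it) {
    bool record = (it >= burn_in);
    for (int j = 0; j < b; ++j) {
      double resid = r[j] - (Rbeta[j] - beta[j]);  // diag(R) == 1
      double pj;
      if (always_in) {
        pj = 1.0;
      } else {
        double l1 = -0.5 * std::log(v_slab) - 0.5 * resid * resid / v_slab;
        double l0 = -0.5 * std::log(v_null) - 0.5 * resid * resid / v_null;
        double lo = log_prior_odds + l1 - l0;
        pj = 1.0 / (1.0 + std::exp(-lo));
      }
      double mu = tau2 * n * resid;
      double newb = 0.0;
      if (unif_rand() < pj) newb = mu + std::sqrt(tau2) * norm_rand();
      double delta = newb - beta[j];
      if (delta != 0.0) {
        for (int l = 0; l < b; ++l) Rbeta[l] += R(l, j) * delta;
        beta[j] = newb;
      }
      if (record) {
        postmean[j] += pj * mu;
        pip[j] += pj;
      }
    }
    if (record) ++kept;
  }
  for (int j = 0; j < b; ++j) {
    postmean[j] /= kept;
    pip[j] /= kept;
  }
  return List::create(_["postmean"] = postmean, _["pip"] = pip);
}
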