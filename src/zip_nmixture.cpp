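#include <Rcpp.h>
using namespace Rcpp;

// Zero-inflated Poisson N-mixture log-likelihood.
//
// y         : sites x visits integer count matrix, NA_INTEGER = missing visit
// log_lambda: per-site log expected abundance (length n_sites)
// logit_p   : sites x visits detection linear predictor on the logit scale;
//             entries for missing visits are ignored
// psi       : zero-inflation probability in [0, 1)
// K         : truncation bound for the latent-abundance sum
//
// Per site i:
//   L_i = psi * I[all observed y_ij = 0]
//       + (1 - psi) * sum_{N=0}^{K} Pois(N; lambda_i) * prod_j Bin(y_ij; N, p_ij)
// The inner sum is accumulated in log space (log-sum-exp). Binomial and
// Poisson terms use a shared lgamma(n+1) lookup table, so the N-loop costs
// one table lookup per observed visit. Logit predictors are clamped to
// +/-35 (|error| < 1e-15 in p) to keep log(p) and log(1-p) finite.
// [[Rcpp::export]]
double zip_nmix_loglik_cpp(IntegerMatrix y, NumericVector log_lambda,
                           NumericMatrix logit_p, double psi, int K) {
  const int n = y.nrow(), J = y.ncol();
  const double log1m_psi = log1p(-psi);
  double total = 0.0;

  // lgam[m] = lgamma(m + 1) = log(m!)
  std::vector<double> lgam(K + 2);
  for (int m = 0; m <= K + 1; ++m) lgam[m] = R::lgammafn(m + 1.0);

  std::vector<double> lp_store(K + 1);
  std::vector<int> yy(J);
  std::vector<double> l1p(J);

  for (int i = 0; i < n; ++i) {
    const double llam = log_lambda[i];
    const double lam = std::exp(llam);

    int nobs = 0, ymax = 0;
    bool all_zero = true;
    double S1 = 0.0, S2 = 0.0;  // sum log(1-p_j); sum y_j*logit(p_j) - log(y_j!)
    for (int j = 0; j < J; ++j) {
      const int yij = y(i, j);
      if (yij == NA_INTEGER) continue;
      double eta = logit_p(i, j);
      if (eta > 35.0) eta = 35.0; else if (eta < -35.0) eta = -35.0;
      const double log1mp = -std::log1p(std::exp(eta));  // log(1 - p)
      yy[nobs] = yij;
      l1p[nobs] = log1mp;
      S1 += log1mp;
      S2 += yij * eta - lgam[yij];
      if (yij > 0) { all_zero = false; if (yij > ymax) ymax = yij; }
      ++nobs;
    }

    // log conditional site likelihood via log-sum-exp over N = ymax..K
    double m = R_NegInf;
    for (int N = ymax; N <= K; ++N) {
      // Poisson: N*llam - lam - lgam[N]; binomials: nobs*lgam[N]
      //   - sum_j lgam[N - y_j] + N*S1 + S2  (choose terms via the table)
      double lp = N * (llam + S1) - lam + S2 + (nobs - 1) * lgam[N];
      for (int j = 0; j < nobs; ++j) lp -= lgam[N - yy[j]];
      lp_store[N] = lp;
      if (lp > m) m = lp;
    }
    double s = 0.0;
    if (R_finite(m)) {
      for (int N = ymax; N <= K; ++N) s += std::exp(lp_store[N] - m);
    }
    const double log_cond = R_finite(m) ? m + std::log(s) : R_NegInf;

    double log_Li;
    if (psi > 0.0 && all_zero) {
      const double a = std::log(psi), b = log1m_psi + log_cond;
      const double mx = std::max(a, b);
      log_Li = mx + std::log(std::exp(a - mx) + std::exp(b - mx));
    } else {
      log_Li = (psi > 0.0 ? log1m_psi : 0.0) + log_cond;
    }
    total += log_Li;
  }
  return total;
}
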