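#include <Rcpp.h>
using namespace Rcpp;

// genomic-cline log-likelihood at one locus for parameters (alpha, beta);
// h-dependent terms are precomputed by the caller.
static double locus_loglik(const int* g, int n,
                           const double* h, const double* hh, const double* h2,
                           double pA, double pB,
                           double alpha, double beta, double eps) {
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    if (g[i] == NA_INTEGER) continue;
    double phi = h[i] + hh[i] * (alpha + beta * h2[i]);
    if (phi < 0.0) phi = 0.0;
    if (phi > 1.0) phi = 1.0;
    double q = phi * pA + (1.0 - phi) * pB;
    if (q < eps) q = eps;
    if (q > 1.0 - eps) q = 1.0 - eps;
    ll += g[i] * std::log(q) + (2 - g[i]) * std::log1p(-q);
  }
  return ll;
}

static double etpi_quantile(std::vector<double> x, double prob) {
  // equal-tail bound via linear interpolation of order statistics (type 7)
  std::sort(x.begin(), x.end());
  int n = x.size();
  double idx = prob * (n - 1);
  int lo = (int)std::floor(idx);
  int hi = (int)std::ceil(idx);
  double w = idx - lo;
  return x[lo] * (1.0 - w) + x[hi] * w;
}

// Per-locus independent random-walk Metropolis on (alpha, beta) with
// Normal(0, prior_sd^2) priors. Proposal scales are tuned during burn-in
// toward ~30% acceptance. Uses R's RNG so set.seed() governs the chains.
// [[Rcpp::export]]
List cline_mcmc_cpp(IntegerMatrix g, NumericVector h,
                    NumericVector pA, NumericVector pB,
                    int n_iter, int burnin, int thin,
                    double prior_sd, double init_scale,
                    double etpi_level) {
  int L = g.nrow(), n = g.ncol();
  if (h.size() != n) stop("h must match the number of individuals");
  std::vector<double> hv(n), hh(n), h2(n);
  for (int i = 0; i < n; ++i) {
    hv[i] = h[i];
    hh[i] = 2.0 * h[i] * (1.0 - h[i]);
    h2[i] = 2.0 * h[i] - 1.0;
  }
  const double eps = 1e-4;
  double tail = (1.0 - etpi_level) / 2.0;
  double prior_var = prior_sd * prior_sd;

  NumericVector a_mean(L), a_lo(L), a_hi(L), b_mean(L), b_lo(L), b_hi(L),
      accept(L);
  std::vector<int> grow(n);

  for (int l = 0; l < L; ++l) {
    for (int i = 0; i < n; ++i) grow[i] = g(l, i);
    double alpha = 0.0, beta = 0.0;
    double sa = init_scale, sb = init_scale;
    double ll = locus_loglik(grow.data(), n, hv.data(), hh.data(), h2.data(),
                             pA[l], pB[l], alpha, beta, eps);
    double lp = ll - (alpha * alpha + beta * beta) / (2.0 * prior_var);
    int tune_acc = 0, tune_n = 0, kept_acc = 0, kept_n = 0;
    std::vector<double> sa_keep, sb_keep;
    sa_keep.reserve((n_iter - burnin) / thin + 1);
    sb_keep.reserve((n_iter - burnin) / thin + 1);

    for (int it = 1; it <= n_iter; ++it) {
      double a_new = alpha + norm_rand() * sa;
      double b_new = beta + norm_rand() * sb;
      double ll_new = locus_loglik(grow.data(), n, hv.data(), hh.data(),
                                   h2.data(), pA[l], pB[l], a_new, b_new, eps);
      double lp_new = ll_new - (a_new * a_new + b_new * b_new) / (2.0 * prior_var);
      bool acc = std::log(unif_rand()) < lp_new - lp;
      if (acc) { alpha = a_new; beta = b_new; lp = lp_new; }
      if (it <= burnin) {
        tune_acc += acc; ++tune_n;
        if (tune_n == 100) {
          double rate = (double)tune_acc / tune_n;
          double f = std::exp((rate - 0.30));
          if (f < 0.5) f = 0.5;
          if (f > 2.0) f = 2.0;
          sa *= f; sb *= f;
          tune_acc = 0; tune_n = 0;
        }
      } else {
        kept_acc += acc; ++kept_n;
        if ((it - burnin) % thin == 0) {
          sa_keep.push_back(alpha);
          sb_keep.push_back(beta);
        }
      }
    }
    double am = 0, bm = 0;
    for (size_t k = 0; k < sa_keep.size(); ++k) { am += sa_keep[k]; bm += sb_keep[k]; }
    am /= sa_keep.size(); bm /= sb_keep.size();
    a_mean[l] = am; b_mean[l] = bm;
    a_lo[l] = etpi_quantile(sa_keep, tail);
    a_hi[l] = etpi_quantile(sa_keep, 1.0 - tail);
    b_lo[l] = etpi_quantile(sb_keep, tail);
    b_hi[l] = etpi_quantile(sb_keep, 1.0 - tail);
    accept[l] = (double)kept_acc / kept_n;
    if (l % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["alpha_mean"] = a_mean, _["alpha_lo"] = a_lo,
                      _["alpha_hi"] = a_hi, _["beta_mean"] = b_mean,
                      _["beta_lo"] = b_lo, _["beta_hi"] = b_hi,
                      _["accept"] = accept);
}
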