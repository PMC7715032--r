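// Sparse accumulation of overlap-normalized pairwise cross-correlations
// into a 3D (spatial bin x time lag) map. For binary spike trains the
// lagged product sum decomposes into a spike-coincidence histogram plus
// overlap spike counts obtainable from prefix sums, so each pair costs
// O(n_x * n_y + n_lags) instead of O(N * n_lags).
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List xcorr_accum_cpp(List spikes, NumericVector mu, NumericVector sigma,
                     int nbins, int max_lag,
                     IntegerVector pair_i, IntegerVector pair_j,
                     IntegerVector bin_fwd, IntegerVector bin_rev,
                     int n_spatial) {
  const int n_tr = spikes.size();
  const int n_lag = 2 * max_lag + 1;
  const int n_pairs = pair_i.size();
  // prefix counts per train: cum[k] = number of spikes at bins < k
  std::vector<std::vector<int> > spk(n_tr);
  std::vector<std::vector<int> > cum(n_tr);
  for (int i = 0; i < n_tr; ++i) {
    IntegerVector s = spikes[i];
    spk[i] = as<std::vector<int> >(s);
    cum[i].assign(nbins + 1, 0);
    for (size_t q = 0; q < spk[i].size(); ++q) cum[i][spk[i][q] + 1] += 1;
    for (int k = 0; k < nbins; ++k) cum[i][k + 1] += cum[i][k];
  }
  NumericVector value((R_xlen_t)n_spatial * n_lag);
  NumericVector cov((R_xlen_t)n_spatial * n_lag);  // unnormalized twin
  IntegerVector count(n_spatial);
  std::vector<double> val(n_lag);
  std::vector<int> coin(n_lag);
  for (int p = 0; p < n_pairs; ++p) {
    const int i = pair_i[p], j = pair_j[p];
    const std::vector<int>& xi = spk[i];
    const std::vector<int>& xj = spk[j];
    std::fill(coin.begin(), coin.end(), 0);
    for (size_t a = 0; a < xi.size(); ++a) {
      const int ta = xi[a];
      for (size_t b = 0; b < xj.size(); ++b) {
        const int d = xj[b] - ta;
        if (d >= -max_lag && d <= max_lag) coin[d + max_lag] += 1;
      }
    }
    const double mx = mu[i], my = mu[j];
    const double inv_ss = 1.0 / (sigma[i] * sigma[j]);
    for (int n = -max_lag; n <= max_lag; ++n) {
      const int lo = n < 0 ? -n : 0;
      const int hi = nbins - 1 - (n > 0 ? n : 0);
      const int L = hi - lo + 1;
      double vv;
      if (L < 2) {
        vv = 0.0;
      } else {
        const double Sx = cum[i][hi + 1] - cum[i][lo];
        const double Sy = cum[j][hi + n + 1] - cum[j][lo + n];
        const double raw = coin[n + max_lag] - my * Sx - mx * Sy +
          (double)L * mx * my;
        vv = raw * inv_ss / L;
      }
      val[n + max_lag] = vv;
    }
    const int bf = bin_fwd[p], br = bin_rev[p];
    double* vf = REAL(value) + (R_xlen_t)bf * n_lag;
    double* vr = REAL(value) + (R_xlen_t)br * n_lag;
    double* cf = REAL(cov) + (R_xlen_t)bf * n_lag;
    double* cr = REAL(cov) + (R_xlen_t)br * n_lag;
    const double ss = sigma[i] * sigma[j];
    for (int n = 0; n < n_lag; ++n) {
      vf[n] += val[n];
      vr[n] += val[n_lag - 1 - n];
      cf[n] += val[n] * ss;
      cr[n] += val[n_lag - 1 - n] * ss;
    }
    count[bf] += 1;
    count[br] += 1;
  }
  return List::create(_["value"] = value, _["cov"] = cov,
                      _["count"] = count);
}
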