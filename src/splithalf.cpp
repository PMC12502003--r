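#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

// Pearson correlation over P pairs; NaN if either side is constant.
double pearson(const std::vector<double>& x, const std::vector<double>& y) {
  const int n = x.size();
  double mx = 0, my = 0;
  for (int i = 0; i < n; ++i) { mx += x[i]; my += y[i]; }
  mx /= n; my /= n;
  double sxx = 0, syy = 0, sxy = 0;
  for (int i = 0; i < n; ++i) {
    const double dx = x[i] - mx, dy = y[i] - my;
    sxx += dx * dx; syy += dy * dy; sxy += dx * dy;
  }
  if (sxx <= 0 || syy <= 0) return NA_REAL;
  return sxy / std::sqrt(sxx * syy);
}

// Permute the trials of participant p (values[start..start+len-1]) into buf
// and return (mean of first half, mean of second half); first half gets the
// extra trial when the count is odd.
inline void split_means(const NumericVector& values, int start, int len,
                        std::vector<double>& buf, double& h1, double& h2) {
  buf.resize(len);
  for (int i = 0; i < len; ++i) buf[i] = values[start + i];
  for (int i = len - 1; i > 0; --i) {  // Fisher-Yates with R's RNG
    int j = static_cast<int>(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(buf[i], buf[j]);
  }
  const int k1 = (len + 1) / 2;
  double s1 = 0, s2 = 0;
  for (int i = 0; i < k1; ++i) s1 += buf[i];
  for (int i = k1; i < len; ++i) s2 += buf[i];
  h1 = s1 / k1;
  h2 = s2 / (len - k1);
}

}  // namespace

// Bootstrap split-half reliability core. Participants' trials are passed as
// one vector with per-participant offsets (0-based) and lengths. Each of
// n_boot draws resamples participants with replacement (identity when
// resample = false), computes n_perm permutation split-half estimates
// (Pearson r across participants between half-means, Spearman-Brown
// corrected), and returns the per-draw mean estimates.
//
// When diff_mode is true a second trial set is supplied (values2 et al.,
// same participant order) and the correlated quantity is the difference of
// half-means (set2 minus set1), each set permuted and halved within itself
// -- the split-half scheme for difference scores such as the flanker
// congruency effect.
// [[Rcpp::export]]
NumericVector splithalf_boot_cpp(const NumericVector values,
                                 const IntegerVector start,
                                 const IntegerVector len,
                                 const NumericVector values2,
                                 const IntegerVector start2,
                                 const IntegerVector len2,
                                 const int n_boot, const int n_perm,
                                 const bool resample, const bool diff_mode) {
  const int P = start.size();
  NumericVector out(n_boot);
  std::vector<int> idx(P);
  std::vector<double> a(P), b(P), buf;

  for (int bt = 0; bt < n_boot; ++bt) {
    if (resample) {
      for (int p = 0; p < P; ++p) {
        int j = static_cast<int>(unif_rand() * P);
        if (j >= P) j = P - 1;
        idx[p] = j;
      }
    } else {
      for (int p = 0; p < P; ++p) idx[p] = p;
    }
    double acc = 0;
    int n_ok = 0;
    for (int pm = 0; pm < n_perm; ++pm) {
      for (int p = 0; p < P; ++p) {
        const int q = idx[p];
        double h1, h2;
        split_means(values, start[q], len[q], buf, h1, h2);
        if (diff_mode) {
          double g1, g2;
          split_means(values2, start2[q], len2[q], buf, g1, g2);
          a[p] = g1 - h1;
          b[p] = g2 - h2;
        } else {
          a[p] = h1;
          b[p] = h2;
        }
      }
      const double r = pearson(a, b);
      if (ISNAN(r) || r <= -1.0) continue;  // Spearman-Brown undefined at r = -1
      acc += 2.0 * r / (1.0 + r);
      ++n_ok;
    }
    out[bt] = (n_ok > 0) ? acc / n_ok : NA_REAL;
  }
  return out;
}
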