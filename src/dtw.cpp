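#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact dynamic-time-warping alignment with steps {(1,1),(1,0),(0,1)},
// boundary anchoring, optional Sakoe-Chiba band |i - j| <= band, and L1 or
// squared pointwise cost. Ties are broken by preferring the diagonal step,
// then the step advancing i. The cumulative cost uses two rolling rows;
// the full predecessor table is kept as one byte per cell for traceback.
// [[Rcpp::export]]
List dtw_cpp(const NumericVector a, const NumericVector b, const int band,
             const bool squared) {
  const int N = a.size(), M = b.size();
  const double INF = std::numeric_limits<double>::infinity();

  // predecessor codes: 1 = diagonal, 2 = from (i-1, j), 3 = from (i, j-1)
  std::vector<unsigned char> step(static_cast<size_t>(N) * M, 0);
  std::vector<double> prev(M, INF), cur(M, INF);

  for (int i = 0; i < N; ++i) {
    int jlo = 0, jhi = M - 1;
    if (band >= 0) {
      jlo = std::max(0, i - band);
      jhi = std::min(M - 1, i + band);
    }
    std::fill(cur.begin(), cur.end(), INF);
    for (int j = jlo; j <= jhi; ++j) {
      double c = std::fabs(a[i] - b[j]);
      if (squared) c *= c;
      if (i == 0 && j == 0) {
        cur[j] = c;
        continue;
      }
      const double d_diag = (i > 0 && j > 0) ? prev[j - 1] : INF;
      const double d_up   = (i > 0) ? prev[j] : INF;
      const double d_left = (j > 0) ? cur[j - 1] : INF;
      unsigned char code = 1;
      double best = d_diag;
      if (d_up < best) { best = d_up; code = 2; }
      if (d_left < best) { best = d_left; code = 3; }
      cur[j] = c + best;
      step[static_cast<size_t>(i) * M + j] = code;
    }
    std::swap(prev, cur);
  }

  const double total = prev[M - 1];
  if (!R_finite(total))
    stop("DTW band is too narrow to connect the endpoints");

  // traceback
  std::vector<int> pi, pj;
  int i = N - 1, j = M - 1;
  while (true) {
    pi.push_back(i + 1);  // 1-based for R
    pj.push_back(j + 1);
    if (i == 0 && j == 0) break;
    const unsigned char code = step[static_cast<size_t>(i) * M + j];
    if (code == 1) { --i; --j; }
    else if (code == 2) { --i; }
    else { --j; }
  }
  std::reverse(pi.begin(), pi.end());
  std::reverse(pj.begin(), pj.end());

  return List::create(_["index_a"] = wrap(pi), _["index_b"] = wrap(pj),
                      _["total_cost"] = total);
}
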