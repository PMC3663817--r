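#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Center-weighted median of a single image plane.
// The center pixel of each window is entered `center_weight` times into the
// multiset before taking the median; borders are handled by edge replication.
// Window size must be odd and >= 3 (validated on the R side).
// [[Rcpp::export(name = ".cw_median_plane")]]
NumericMatrix cw_median_plane(NumericMatrix img, int window, int center_weight) {
  const int nr = img.nrow(), nc = img.ncol();
  const int half = window / 2;
  const int nval = window * window - 1 + center_weight;
  NumericMatrix out(nr, nc);
  std::vector<double> buf(nval);

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int k = 0;
      for (int dj = -half; dj <= half; ++dj) {
        int jj = std::min(std::max(j + dj, 0), nc - 1);
        for (int di = -half; di <= half; ++di) {
          int ii = std::min(std::max(i + di, 0), nr - 1);
          if (di == 0 && dj == 0) {
            for (int w = 0; w < center_weight; ++w) buf[k++] = img(ii, jj);
          } else {
            buf[k++] = img(ii, jj);
          }
        }
      }
      // median of nval values; nval parity depends on center_weight
      std::vector<double>::iterator mid = buf.begin() + nval / 2;
      std::nth_element(buf.begin(), mid, buf.end());
      if (nval % 2 == 1) {
        out(i, j) = *mid;
      } else {
        double hi = *mid;
        double lo = *std::max_element(buf.begin(), mid);
        out(i, j) = 0.5 * (lo + hi);
      }
    }
  }
  return out;
}
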