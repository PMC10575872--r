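#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Per-row median of a pixels x layers matrix, ignoring NA. Rows with no
// finite value yield NA. This is the hot loop behind gap-filling and
// annual compositing; stack depths are small (a handful of scenes).
// [[Rcpp::export(name = ".stack_median_cpp")]]
NumericVector stack_median_cpp(NumericMatrix m) {
  const int n = m.nrow(), k = m.ncol();
  NumericVector out(n);
  std::vector<double> buf;
  buf.reserve(k);
  for (int i = 0; i < n; ++i) {
    buf.clear();
    for (int j = 0; j < k; ++j) {
      double v = m(i, j);
      if (!NumericVector::is_na(v)) buf.push_back(v);
    }
    const int c = (int) buf.size();
    if (c == 0) {
      out[i] = NA_REAL;
    } else {
      std::nth_element(buf.begin(), buf.begin() + c / 2, buf.end());
      double hi = buf[c / 2];
      if (c % 2 == 1) {
        out[i] = hi;
      } else {
        // even count: mean of the two middle order statistics
        double lo = *std::max_element(buf.begin(), buf.begin() + c / 2);
        out[i] = (lo + hi) / 2.0;
      }
    }
  }
  return out;
}
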