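#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// mirror (reflect-without-repeat) index into [0, n)
static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  const int p = 2 * (n - 1);
  i %= p;
  if (i < 0) i += p;
  return (i >= n) ? p - i : i;
}

// Exact square median filter with mirror boundary handling.
// [[Rcpp::export(name = ".median_filter_cpp")]]
NumericMatrix median_filter_cpp(const NumericMatrix& m, const int width) {
  const int nr = m.nrow(), nc = m.ncol();
  const int half = (width - 1) / 2;
  const int k = width * width;
  NumericMatrix out(nr, nc);
  std::vector<double> buf(k);
  std::vector<int> ri(width), ci(width);
  for (int j = 0; j < nc; ++j) {
    for (int b = -half; b <= half; ++b) ci[b + half] = reflect(j + b, nc);
    for (int i = 0; i < nr; ++i) {
      for (int a = -half; a <= half; ++a) ri[a + half] = reflect(i + a, nr);
      int t = 0;
      for (int b = 0; b < width; ++b)
        for (int a = 0; a < width; ++a) buf[t++] = m(ri[a], ci[b]);
      std::nth_element(buf.begin(), buf.begin() + k / 2, buf.end());
      out(i, j) = buf[k / 2];
    }
  }
  return out;
}
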