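#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Median over the first (trial) dimension of a trials x channels x time
// array, returned as a channels x time matrix. Hot path of the iterative
// decomposition, hence compiled: R-level apply() over ~30k cells dominates
// the runtime otherwise.
// [[Rcpp::export(name = ".medianOverTrials")]]
NumericMatrix medianOverTrials(NumericVector arr) {
  IntegerVector dims = arr.attr("dim");
  if (dims.size() != 3) stop("expected a 3-D array");
  const int n = dims[0], nc = dims[1], nt = dims[2];
  NumericMatrix out(nc, nt);
  std::vector<double> buf(n);
  const double *p = arr.begin();
  const int half = n / 2;
  for (int t = 0; t < nt; ++t) {
    for (int c = 0; c < nc; ++c) {
      const double *col = p + (size_t)n * (c + (size_t)nc * t);
      std::copy(col, col + n, buf.begin());
      std::nth_element(buf.begin(), buf.begin() + half, buf.end());
      double m = buf[half];
      if (n % 2 == 0) {
        double lo = *std::max_element(buf.begin(), buf.begin() + half);
        m = (m + lo) / 2.0;
      }
      out(c, t) = m;
    }
  }
  return out;
}
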