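#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// One pass of a second-order-section cascade, direct-form II transposed.
// sos rows: b0 b1 b2 a0(=1) a1 a2; first-order sections have b2 = a2 = 0.
static void run_cascade(std::vector<double>& x, const NumericMatrix& sos) {
  const int ns = sos.nrow();
  const size_t n = x.size();
  for (int s = 0; s < ns; ++s) {
    const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    const double a1 = sos(s, 4), a2 = sos(s, 5);
    double z1 = 0.0, z2 = 0.0;
    for (size_t i = 0; i < n; ++i) {
      const double xi = x[i];
      const double yi = b0 * xi + z1;
      z1 = b1 * xi - a1 * yi + z2;
      z2 = b2 * xi - a2 * yi;
      x[i] = yi;
    }
  }
}

// Filter a signal through an SOS cascade; zero_phase runs the cascade
// forward and backward over a zero-padded copy so the net phase is zero and
// the magnitude response is squared.
// [[Rcpp::export]]
NumericVector sosfilt_cpp(NumericMatrix sos, NumericVector x,
                          bool zero_phase, int pad) {
  const size_t n = x.size();
  if (pad < 0) pad = 0;
  std::vector<double> buf(n + 2 * static_cast<size_t>(pad), 0.0);
  std::copy(x.begin(), x.end(), buf.begin() + pad);
  run_cascade(buf, sos);
  if (zero_phase) {
    std::reverse(buf.begin(), buf.end());
    run_cascade(buf, sos);
    std::reverse(buf.begin(), buf.end());
  }
  NumericVector out(n);
  std::copy(buf.begin() + pad, buf.begin() + pad + n, out.begin());
  return out;
}
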