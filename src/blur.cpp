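#include <Rcpp.h>
using namespace Rcpp;

// Separable Gaussian blur with mirror boundary. Kernel truncated at 3 sigma.
// [[Rcpp::export]]
NumericMatrix gauss_blur_cpp(NumericMatrix img, double sigma) {
  int nr = img.nrow(), nc = img.ncol();
  if (sigma <= 0.0) return clone(img);
  int radius = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * radius + 1);
  double s = 0.0;
  for (int i = -radius; i <= radius; ++i) {
    k[i + radius] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + radius];
  }
  for (size_t i = 0; i < k.size(); ++i) k[i] /= s;

  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double a = 0.0;
      for (int d = -radius; d <= radius; ++d) {
        int ii = i + d;
        if (ii < 0) ii = -ii - 1;
        if (ii >= nr) ii = 2 * nr - ii - 1;
        a += k[d + radius] * img(ii, j);
      }
      tmp(i, j) = a;
    }
  }
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      double a = 0.0;
      for (int d = -radius; d <= radius; ++d) {
        int jj = j + d;
        if (jj < 0) jj = -jj - 1;
        if (jj >= nc) jj = 2 * nc - jj - 1;
        a += k[d + radius] * tmp(i, jj);
      }
      out(i, j) = a;
    }
  }
  return out;
}
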