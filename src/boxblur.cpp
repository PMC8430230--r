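#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// one sliding-window mean pass along columns, replicated boundary
static void box_pass_cols(std::vector<double> &a, int nr, int nc, int h) {
  if (h <= 0) return;
  std::vector<double> tmp(nr);
  for (int j = 0; j < nc; ++j) {
    double *col = a.data() + (size_t)j * nr;
    double s = 0;
    // replicate edges: prime the window
    for (int k = -h; k <= h; ++k) {
      int ii = k < 0 ? 0 : (k >= nr ? nr - 1 : k);
      s += col[ii];
    }
    double w = 2 * h + 1;
    for (int i = 0; i < nr; ++i) {
      tmp[i] = s / w;
      int add = i + h + 1; if (add >= nr) add = nr - 1;
      int rem = i - h; if (rem < 0) rem = 0;
      s += col[add] - col[rem];
    }
    std::copy(tmp.begin(), tmp.end(), col);
  }
}

static void transpose(const std::vector<double> &in, std::vector<double> &out,
                      int nr, int nc) {
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out[(size_t)i * nc + j] = in[(size_t)j * nr + i];
}

// Fast approximately-Gaussian blur: three sliding-box passes per dimension
// (the cascade of three boxes of width w has sd sqrt((w^2 - 1) / 4), close
// to Gaussian by the central limit theorem). Cost is independent of sigma,
// which matters for the synthetic renderer's large defocus kernels.
// [[Rcpp::export]]
NumericMatrix box_blur_cpp(NumericMatrix img, double sigma) {
  int nr = img.nrow(), nc = img.ncol();
  if (sigma <= 0) return clone(img);
  // three equal boxes of half-width h: total variance 3 * ((2h+1)^2 - 1)/12
  int h = (int)std::round((std::sqrt(4.0 * sigma * sigma + 1.0) - 1.0) / 2.0);
  if (h < 1) h = 1;
  std::vector<double> a((size_t)nr * nc), b((size_t)nr * nc);
  std::copy(img.begin(), img.end(), a.begin());
  for (int p = 0; p < 3; ++p) box_pass_cols(a, nr, nc, h);
  transpose(a, b, nr, nc);
  for (int p = 0; p < 3; ++p) box_pass_cols(b, nc, nr, h);
  NumericMatrix out(nr, nc);
  std::vector<double> c((size_t)nr * nc);
  transpose(b, c, nc, nr);
  std::copy(c.begin(), c.end(), out.begin());
  return out;
}
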