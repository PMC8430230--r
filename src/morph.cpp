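#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// van Herk / Gil-Werman sliding window min or max over each column,
// centred window of half-width h; out-of-image samples are ignored.
static void column_extreme(const double *in, double *out, int nr, int nc,
                           int h, bool mini) {
  int w = 2 * h + 1;
  double sentinel = mini ? R_PosInf : R_NegInf;
  int np = nr + 2 * h;   // pad with sentinels so every window is interior
  std::vector<double> pa(np), g(np), d(np);
  for (int j = 0; j < nc; ++j) {
    const double *a = in + (size_t)j * nr;
    double *o = out + (size_t)j * nr;
    if (h == 0) { for (int i = 0; i < nr; ++i) o[i] = a[i]; continue; }
    for (int k = 0; k < np; ++k) {
      pa[k] = (k < h || k >= nr + h) ? sentinel : a[k - h];
    }
    for (int i = 0; i < np; ++i) {
      if (i % w == 0) g[i] = pa[i];
      else g[i] = mini ? std::min(g[i - 1], pa[i]) : std::max(g[i - 1], pa[i]);
    }
    for (int i = np - 1; i >= 0; --i) {
      if (i == np - 1 || (i + 1) % w == 0) d[i] = pa[i];
      else d[i] = mini ? std::min(d[i + 1], pa[i]) : std::max(d[i + 1], pa[i]);
    }
    for (int i = 0; i < nr; ++i) {
      // window [i - h, i + h] in original = [i, i + 2h] in padded
      double v = d[i], gv = g[i + 2 * h];
      o[i] = mini ? std::min(v, gv) : std::max(v, gv);
    }
  }
}

// grayscale erosion (mini = true) or dilation over a disc of given radius:
// the disc is decomposed into vertical chords (one half-height per column
// offset), each handled by a sliding-window pass, then combined across
// offsets.
static NumericMatrix disc_extreme(const NumericMatrix &img, double radius,
                                  bool mini) {
  int nr = img.nrow(), nc = img.ncol();
  int r = (int)std::floor(radius);
  std::vector<int> hs(r + 1);
  for (int dj = 0; dj <= r; ++dj) {
    hs[dj] = (int)std::floor(std::sqrt(radius * radius - (double)dj * dj));
  }
  // vertical pass per distinct half-height
  std::vector<int> distinct;
  for (int dj = 0; dj <= r; ++dj) {
    if (std::find(distinct.begin(), distinct.end(), hs[dj]) == distinct.end())
      distinct.push_back(hs[dj]);
  }
  std::vector<NumericMatrix> vert(distinct.size());
  for (size_t k = 0; k < distinct.size(); ++k) {
    vert[k] = NumericMatrix(nr, nc);
    column_extreme(&img(0, 0), &vert[k](0, 0), nr, nc, distinct[k], mini);
  }
  std::vector<int> which_h(r + 1);
  for (int dj = 0; dj <= r; ++dj) {
    which_h[dj] = std::find(distinct.begin(), distinct.end(), hs[dj]) -
      distinct.begin();
  }
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    double *o = &out(0, j);
    for (int i = 0; i < nr; ++i) o[i] = mini ? R_PosInf : R_NegInf;
    for (int dj = -r; dj <= r; ++dj) {
      int jj = j + dj;
      if (jj < 0 || jj >= nc) continue;
      const double *v = &vert[which_h[std::abs(dj)]](0, jj);
      if (mini) { for (int i = 0; i < nr; ++i) if (v[i] < o[i]) o[i] = v[i]; }
      else      { for (int i = 0; i < nr; ++i) if (v[i] > o[i]) o[i] = v[i]; }
    }
  }
  return out;
}

// Grayscale morphological opening (erosion then dilation) with a disc of the
// given radius: the rolling-ball style background estimate used by the
// granule detector.
// [[Rcpp::export]]
NumericMatrix gray_opening_cpp(NumericMatrix img, double radius) {
  if (radius <= 0) return clone(img);
  NumericMatrix e = disc_extreme(img, radius, true);
  return disc_extreme(e, radius, false);
}
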