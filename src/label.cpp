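#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labelling by iterative flood fill.
// connectivity must be 4 or 8; labels are assigned in column-major scan
// order of the first pixel encountered, starting at 1.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");

  const int dx4[4] = {0, 0, -1, 1};
  const int dy4[4] = {-1, 1, 0, 0};
  const int dx8[8] = {0, 0, -1, 1, -1, -1, 1, 1};
  const int dy8[8] = {-1, 1, 0, 0, -1, 1, -1, 1};
  const int *dx = (connectivity == 4) ? dx4 : dx8;
  const int *dy = (connectivity == 4) ? dy4 : dy8;
  int nnb = connectivity;

  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) != TRUE || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.clear();
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int d = 0; d < nnb; ++d) {
          int qi = pi + dy[d], qj = pj + dx[d];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (mask(qi, qj) == TRUE && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            stack.push_back(qi + qj * nr);
          }
        }
      }
    }
  }
  return lab;
}
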