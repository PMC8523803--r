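#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// 8-connected component labeling of a binary mask (iterative flood fill);
// 8-connectivity preserves thin diagonal strands.
// [[Rcpp::export]]
IntegerMatrix label_components8_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      if (!mask(r0, c0) || lab(r0, c0) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(c0 * nr + r0);
      lab(r0, c0) = next;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int r = idx % nr, c = idx / nr;
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (mask(rr, cc) && lab(rr, cc) == 0) {
              lab(rr, cc) = next;
              stack.push_back(cc * nr + rr);
            }
          }
        }
      }
    }
  }
  return lab;
}
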