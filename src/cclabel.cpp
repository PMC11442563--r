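// Connected-component labeling of a binary mask under 4- or 8-connectivity,
// iterative flood fill. Labels are 1..n in scan order of component seeds.

#include <Rcpp.h>
#include <vector>

// [[Rcpp::export]]
Rcpp::IntegerMatrix label_components(const Rcpp::LogicalMatrix& mask,
                                     const int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    Rcpp::stop("connectivity must be 4 or 8");
  const int H = mask.nrow(), W = mask.ncol();
  Rcpp::IntegerMatrix lab(H, W);
  const int di8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 4) ? 4 : 8;
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(i + j * H);
      lab(i, j) = next;
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int pi = p % H, pj = p / H;
        for (int q = 0; q < nn; ++q) {
          const int qi = pi + di8[q], qj = pj + dj8[q];
          if (qi < 0 || qi >= H || qj < 0 || qj >= W) continue;
          if (mask(qi, qj) && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            stack.push_back(qi + qj * H);
          }
        }
      }
    }
  }
  return lab;
}
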