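// Connected-component labelling on binary masks (iterative flood fill).

#include <Rcpp.h>
#include <vector>

// [[Rcpp::export]]
Rcpp::IntegerMatrix cc_label_cpp(Rcpp::LogicalMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  Rcpp::IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<std::pair<int, int>> stack;
  const int n8dy[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int n8dx[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int n4dy[4] = {-1, 0, 0, 1};
  const int n4dx[4] = {0, -1, 1, 0};
  const int nn = (connectivity == 8) ? 8 : 4;
  const int* dy = (connectivity == 8) ? n8dy : n4dy;
  const int* dx = (connectivity == 8) ? n8dx : n4dx;
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      if (!mask(y, x) || lab(y, x) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back({y, x});
      lab(y, x) = next;
      while (!stack.empty()) {
        auto [cy, cx] = stack.back();
        stack.pop_back();
        for (int k = 0; k < nn; ++k) {
          const int ny = cy + dy[k], nx = cx + dx[k];
          if (ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
          if (mask(ny, nx) && lab(ny, nx) == 0) {
            lab(ny, nx) = next;
            stack.push_back({ny, nx});
          }
        }
      }
    }
  }
  return lab;
}
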