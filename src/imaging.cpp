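#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <queue>

using namespace Rcpp;

// Median filter with reflect padding and lower-median selection.
// The window need not be odd-sized: the output pixel sits at offset
// (floor((wh-1)/2), floor((ww-1)/2)) from the window's top-left corner,
// so even windows are anchored deterministically.
// [[Rcpp::export]]
IntegerMatrix median_filter_cpp(const IntegerMatrix &img, int wh, int ww) {
  const int nr = img.nrow(), nc = img.ncol();
  if (wh < 1 || ww < 1)
    stop("window dimensions must be >= 1");
  if (wh > nr || ww > nc)
    stop("window (%d x %d) larger than image (%d x %d)", wh, ww, nr, nc);
  const int orow = (wh - 1) / 2, ocol = (ww - 1) / 2;
  const int n = wh * ww;
  const int med = (n - 1) / 2;  // lower median, 0-based
  IntegerMatrix out(nr, nc);
  std::vector<int> buf(n);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      int idx = 0;
      for (int dr = 0; dr < wh; ++dr) {
        int rr = r - orow + dr;
        if (rr < 0) rr = -rr - 1;            // reflect
        else if (rr >= nr) rr = 2 * nr - rr - 1;
        for (int dc = 0; dc < ww; ++dc) {
          int cc = c - ocol + dc;
          if (cc < 0) cc = -cc - 1;
          else if (cc >= nc) cc = 2 * nc - cc - 1;
          buf[idx++] = img(rr, cc);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + med, buf.end());
      out(r, c) = buf[med];
    }
  }
  return out;
}

// Connected-component labelling of a logical mask with 8- or 4-connectivity.
// Labels are 1..K in order of first (column-major) encounter; background is 0.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(const LogicalMatrix &mask, int conn = 8) {
  if (conn != 4 && conn != 8)
    stop("conn must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pr = p % nr, pc = p / nr;
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            if (conn == 4 && dr != 0 && dc != 0) continue;
            int rr = pr + dr, cc = pc + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (mask(rr, cc) && !lab(rr, cc)) {
              lab(rr, cc) = next;
              stack.push_back(rr + cc * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Background pixels 4-connected to the frame border. Everything else in the
// background is a hole. Foreground is taken 8-connected, so its complement
// uses 4-connectivity (the standard dual pairing).
// [[Rcpp::export]]
LogicalMatrix outside_background_cpp(const LogicalMatrix &mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix outside(nr, nc);
  std::fill(outside.begin(), outside.end(), false);
  std::queue<int> q;
  auto push = [&](int r, int c) {
    if (r < 0 || r >= nr || c < 0 || c >= nc) return;
    if (mask(r, c) || outside(r, c)) return;
    outside(r, c) = true;
    q.push(r + c * nr);
  };
  for (int r = 0; r < nr; ++r) { push(r, 0); push(r, nc - 1); }
  for (int c = 0; c < nc; ++c) { push(0, c); push(nr - 1, c); }
  while (!q.empty()) {
    int p = q.front(); q.pop();
    int r = p % nr, c = p / nr;
    push(r - 1, c); push(r + 1, c); push(r, c - 1); push(r, c + 1);
  }
  return outside;
}
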