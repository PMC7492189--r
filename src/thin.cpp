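#include <Rcpp.h>
using namespace Rcpp;

// Zhang-Suen thinning of a binary mask (row-major logic on an R column-major
// matrix). Border pixels are never ink by contract (callers pad); we still
// guard indices. Returns a 1-pixel-wide, 8-connected skeleton.

static inline int px(const IntegerMatrix &m, int r, int c) {
  if (r < 0 || c < 0 || r >= m.nrow() || c >= m.ncol()) return 0;
  return m(r, c);
}

// [[Rcpp::export]]
IntegerMatrix zhang_suen_thin(IntegerMatrix mask) {
  IntegerMatrix m = clone(mask);
  int nr = m.nrow(), nc = m.ncol();
  bool changed = true;
  std::vector<int> delr, delc;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      delr.clear(); delc.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!m(r, c)) continue;
          // neighbours clockwise from north: p2..p9
          int p2 = px(m, r - 1, c),     p3 = px(m, r - 1, c + 1);
          int p4 = px(m, r, c + 1),     p5 = px(m, r + 1, c + 1);
          int p6 = px(m, r + 1, c),     p7 = px(m, r + 1, c - 1);
          int p8 = px(m, r, c - 1),     p9 = px(m, r - 1, c - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0) continue;
            if (p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0) continue;
            if (p2 * p6 * p8 != 0) continue;
          }
          delr.push_back(r); delc.push_back(c);
        }
      }
      if (!delr.empty()) changed = true;
      for (size_t i = 0; i < delr.size(); ++i) m(delr[i], delc[i]) = 0;
    }
  }
  return m;
}

// Count of ink neighbours in the 8-neighbourhood, per pixel.
// [[Rcpp::export]]
IntegerMatrix neighbor_count8(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int s = 0;
      for (int dc = -1; dc <= 1; ++dc)
        for (int dr = -1; dr <= 1; ++dr) {
          if (dr == 0 && dc == 0) continue;
          s += px(mask, r + dr, c + dc);
        }
      out(r, c) = s;
    }
  return out;
}

// Crossing number: 0->1 transitions around the 8-neighbourhood circle
// (p2..p9,p2). Skeleton pixels with >= 3 transitions are true branch points;
// staircase pixels on diagonals have 2 despite 3+ raw neighbours.
// [[Rcpp::export]]
IntegerMatrix transition_count8(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int p[8] = { px(mask, r - 1, c),     px(mask, r - 1, c + 1),
                   px(mask, r, c + 1),     px(mask, r + 1, c + 1),
                   px(mask, r + 1, c),     px(mask, r + 1, c - 1),
                   px(mask, r, c - 1),     px(mask, r - 1, c - 1) };
      int a = 0;
      for (int k = 0; k < 8; ++k) a += (p[k] == 0 && p[(k + 1) % 8] == 1);
      out(r, c) = a;
    }
  return out;
}

// Label 8-connected components of a binary mask; 0 = background, labels are
// assigned in column-major scan order of each component's first pixel.
// [[Rcpp::export]]
IntegerMatrix label_components8(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      stack.clear();
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        for (int dc = -1; dc <= 1; ++dc)
          for (int dr = -1; dr <= 1; ++dr) {
            int r2 = rr + dr, c2 = cc + dc;
            if (r2 < 0 || c2 < 0 || r2 >= nr || c2 >= nc) continue;
            if (mask(r2, c2) && !lab(r2, c2)) {
              lab(r2, c2) = next;
              stack.push_back(r2 + c2 * nr);
            }
          }
      }
    }
  return lab;
}
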