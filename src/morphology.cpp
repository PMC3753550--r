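#include <Rcpp.h>
using namespace Rcpp;

// Zhang-Suen binary thinning to a 1-px skeleton. Pixels outside the image
// count as background. Deletions within each sub-iteration are simultaneous.
// [[Rcpp::export(name = ".zhangSuenThin")]]
IntegerMatrix zhangSuenThin(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix img(clone(mask));
  auto at = [&](int r, int c) -> int {
    if (r < 0 || r >= nr || c < 0 || c >= nc) return 0;
    return img(r, c) != 0 ? 1 : 0;
  };
  std::vector<std::pair<int, int> > del;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int step = 0; step < 2; ++step) {
      del.clear();
      for (int r = 0; r < nr; ++r) {
        for (int c = 0; c < nc; ++c) {
          if (!img(r, c)) continue;
          int p2 = at(r - 1, c), p3 = at(r - 1, c + 1), p4 = at(r, c + 1),
              p5 = at(r + 1, c + 1), p6 = at(r + 1, c), p7 = at(r + 1, c - 1),
              p8 = at(r, c - 1), p9 = at(r - 1, c - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int seq[9] = {p2, p3, p4, p5, p6, p7, p8, p9, p2};
          int A = 0;
          for (int i = 0; i < 8; ++i)
            if (seq[i] == 0 && seq[i + 1] == 1) ++A;
          if (A != 1) continue;
          if (step == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          del.push_back(std::make_pair(r, c));
        }
      }
      if (!del.empty()) {
        changed = true;
        for (size_t i = 0; i < del.size(); ++i)
          img(del[i].first, del[i].second) = 0;
      }
    }
  }
  return img;
}

// 8-connected component labeling; labels 1..K assigned in column-major scan
// order of each component's first pixel (deterministic).
// [[Rcpp::export(name = ".label8")]]
IntegerMatrix label8(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      if (!mask(r0, c0) || lab(r0, c0)) continue;
      ++next;
      lab(r0, c0) = next;
      stack.push_back(r0 + c0 * nr);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int r = idx % nr, c = idx / nr;
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            if (!dr && !dc) continue;
            int rr = r + dr, cc = c + dc;
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
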