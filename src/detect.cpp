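// Windowed local-maximum spot detection for STED-style intensity images.
//
// A pixel is a candidate center iff it is >= every pixel inside the circular
// window centered on it, strictly greater than at least one of them, and its
// own intensity exceeds `min_intensity`. Connected plateaus of equal-valued
// candidates (8-connectivity) are collapsed to their centroid pixel.

#include <Rcpp.h>
#include <cmath>
#include <queue>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export(name = ".cpp_detect_maxima")]]
IntegerMatrix cpp_detect_maxima(NumericMatrix img, int window,
                                double min_intensity) {
  if (window < 3 || window % 2 == 0)
    stop("window must be an odd integer >= 3");
  const int nr = img.nrow(), nc = img.ncol();
  if (window > nr || window > nc) stop("window larger than image");
  const int rad = window / 2;
  const double rad2 = rad * rad + 1e-9;

  // circular window offsets
  std::vector<int> offr, offc;
  for (int dr = -rad; dr <= rad; ++dr)
    for (int dc = -rad; dc <= rad; ++dc)
      if (dr * dr + dc * dc <= rad2 && !(dr == 0 && dc == 0)) {
        offr.push_back(dr);
        offc.push_back(dc);
      }
  const int noff = (int)offr.size();

  std::vector<char> cand((size_t)nr * nc, 0);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double v = img(r, c);
      if (!(v > min_intensity)) continue;
      bool is_max = true, strict = false;
      for (int q = 0; q < noff; ++q) {
        int rr = r + offr[q], cc = c + offc[q];
        if (rr < 0 || cc < 0 || rr >= nr || cc >= nc) continue;
        double w = img(rr, cc);
        if (w > v) {
          is_max = false;
          break;
        }
        if (w < v) strict = true;
      }
      if (is_max && strict) cand[(size_t)c * nr + r] = 1;
    }
  }

  // collapse connected equal-valued candidate plateaus to their centroid
  std::vector<char> seen((size_t)nr * nc, 0);
  std::vector<int> out_r, out_c;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      size_t id = (size_t)c * nr + r;
      if (!cand[id] || seen[id]) continue;
      double v = img(r, c);
      std::queue<std::pair<int, int> > bfs;
      std::vector<std::pair<int, int> > comp;
      bfs.push(std::make_pair(r, c));
      seen[id] = 1;
      while (!bfs.empty()) {
        std::pair<int, int> p = bfs.front();
        bfs.pop();
        comp.push_back(p);
        for (int dr = -1; dr <= 1; ++dr)
          for (int dc = -1; dc <= 1; ++dc) {
            int rr = p.first + dr, cc = p.second + dc;
            if (rr < 0 || cc < 0 || rr >= nr || cc >= nc) continue;
            size_t jd = (size_t)cc * nr + rr;
            if (cand[jd] && !seen[jd] && img(rr, cc) == v) {
              seen[jd] = 1;
              bfs.push(std::make_pair(rr, cc));
            }
          }
      }
      double mr = 0, mc = 0;
      for (size_t q = 0; q < comp.size(); ++q) {
        mr += comp[q].first;
        mc += comp[q].second;
      }
      out_r.push_back((int)std::lround(mr / comp.size()));
      out_c.push_back((int)std::lround(mc / comp.size()));
    }
  }

  IntegerMatrix centers((int)out_r.size(), 2);
  for (int q = 0; q < (int)out_r.size(); ++q) {
    centers(q, 0) = out_r[q];  // 0-based row
    centers(q, 1) = out_c[q];  // 0-based col
  }
  return centers;
}
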