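#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// All neighbourhood filters use replicate padding: out-of-range coordinates
// are clamped to the nearest edge pixel.
static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Rank filter over an arbitrary offset set. type: 0 = median, 1 = max, 2 = min.
// [[Rcpp::export]]
NumericMatrix cpp_rank_filter(NumericMatrix img, IntegerVector dx,
                              IntegerVector dy, int type) {
  const int nr = img.nrow(), nc = img.ncol(), k = dx.size();
  NumericMatrix out(nr, nc);
  std::vector<double> buf(k);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      for (int m = 0; m < k; ++m) {
        int ii = clampi(i + dx[m], 0, nr - 1);
        int jj = clampi(j + dy[m], 0, nc - 1);
        buf[m] = img(ii, jj);
      }
      double v;
      if (type == 1) {
        v = *std::max_element(buf.begin(), buf.end());
      } else if (type == 2) {
        v = *std::min_element(buf.begin(), buf.end());
      } else {
        std::nth_element(buf.begin(), buf.begin() + k / 2, buf.end());
        v = buf[k / 2];
        if (k % 2 == 0) {
          double lo = *std::max_element(buf.begin(), buf.begin() + k / 2);
          v = (v + lo) / 2.0;
        }
      }
      out(i, j) = v;
    }
  }
  return out;
}

// ImageJ-style Remove Outliers: replace a pixel by the neighbourhood median
// only when it deviates from that median by strictly more than `threshold`
// in the stated polarity.
// [[Rcpp::export]]
NumericMatrix cpp_remove_outliers(NumericMatrix img, IntegerVector dx,
                                  IntegerVector dy, double threshold,
                                  bool bright) {
  const int nr = img.nrow(), nc = img.ncol(), k = dx.size();
  NumericMatrix out(nr, nc);
  std::vector<double> buf(k);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      for (int m = 0; m < k; ++m) {
        int ii = clampi(i + dx[m], 0, nr - 1);
        int jj = clampi(j + dy[m], 0, nc - 1);
        buf[m] = img(ii, jj);
      }
      std::nth_element(buf.begin(), buf.begin() + k / 2, buf.end());
      double med = buf[k / 2];
      if (k % 2 == 0) {
        double lo = *std::max_element(buf.begin(), buf.begin() + k / 2);
        med = (med + lo) / 2.0;
      }
      double p = img(i, j);
      double dev = bright ? (p - med) : (med - p);
      out(i, j) = (dev > threshold) ? med : p;
    }
  }
  return out;
}

// Non-flat grayscale erosion/dilation with structuring-element heights h:
// erosion(p)  = min over offsets of img(p+o) - h(o)
// dilation(p) = max over offsets of img(p+o) + h(o)
// [[Rcpp::export]]
NumericMatrix cpp_grey_morph(NumericMatrix img, IntegerVector dx,
                             IntegerVector dy, NumericVector h, bool dilatep) {
  const int nr = img.nrow(), nc = img.ncol(), k = dx.size();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double v = dilatep ? R_NegInf : R_PosInf;
      for (int m = 0; m < k; ++m) {
        int ii = clampi(i + dx[m], 0, nr - 1);
        int jj = clampi(j + dy[m], 0, nc - 1);
        double x = dilatep ? img(ii, jj) + h[m] : img(ii, jj) - h[m];
        if (dilatep ? (x > v) : (x < v)) v = x;
      }
      out(i, j) = v;
    }
  }
  return out;
}

static inline int at(const IntegerMatrix &m, int i, int j) {
  if (i < 0 || j < 0 || i >= m.nrow() || j >= m.ncol()) return 0;
  return m(i, j);
}

// Neighbours in clockwise order starting north (ImageJ convention P2..P9).
static void nbrs(const IntegerMatrix &m, int i, int j, int p[8]) {
  p[0] = at(m, i - 1, j);     // N
  p[1] = at(m, i - 1, j + 1); // NE
  p[2] = at(m, i, j + 1);     // E
  p[3] = at(m, i + 1, j + 1); // SE
  p[4] = at(m, i + 1, j);     // S
  p[5] = at(m, i + 1, j - 1); // SW
  p[6] = at(m, i, j - 1);     // W
  p[7] = at(m, i - 1, j - 1); // NW
}

// Zhang-Suen thinning to a 1-pixel-wide, topology-preserving skeleton,
// followed by a cleanup pass deleting simple pixels left in solid 2x2 blocks
// (a known staircase artifact of the two-subiteration scheme).
// [[Rcpp::export]]
IntegerMatrix cpp_thin(IntegerMatrix mask) {
  IntegerMatrix m = clone(mask);
  const int nr = m.nrow(), nc = m.ncol();
  bool changed = true;
  int p[8];
  std::vector<std::pair<int, int> > kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
          if (!m(i, j)) continue;
          nbrs(m, i, j, p);
          int B = 0, A = 0;
          for (int t = 0; t < 8; ++t) {
            B += p[t];
            if (!p[t] && p[(t + 1) % 8]) ++A;
          }
          if (B < 2 || B > 6 || A != 1) continue;
          // p[0]=N, p[2]=E, p[4]=S, p[6]=W
          if (pass == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;
            if (p[2] * p[4] * p[6] != 0) continue;
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;
            if (p[0] * p[4] * p[6] != 0) continue;
          }
          kill.push_back(std::make_pair(i, j));
        }
      }
      for (size_t t = 0; t < kill.size(); ++t)
        m(kill[t].first, kill[t].second) = 0;
      if (!kill.empty()) changed = true;
    }
  }
  // cleanup: remove simple pixels participating in a solid 2x2 block
  changed = true;
  while (changed) {
    changed = false;
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        if (!m(i, j)) continue;
        bool block = false;
        for (int a = -1; a <= 0 && !block; ++a)
          for (int b = -1; b <= 0 && !block; ++b)
            if (at(m, i + a, j + b) && at(m, i + a + 1, j + b) &&
                at(m, i + a, j + b + 1) && at(m, i + a + 1, j + b + 1))
              block = true;
        if (!block) continue;
        nbrs(m, i, j, p);
        int B = 0, A = 0;
        for (int t = 0; t < 8; ++t) {
          B += p[t];
          if (!p[t] && p[(t + 1) % 8]) ++A;
        }
        if (A == 1 && B > 1) {
          m(i, j) = 0;
          changed = true;
        }
      }
    }
  }
  return m;
}
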