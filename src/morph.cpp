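#include <Rcpp.h>
#include <deque>
#include <map>
#include <cmath>
#include <functional>
using namespace Rcpp;

// Sliding-window extreme (min if takeMin) along each row, window = 2*half+1
// centred, out-of-image positions ignored (neighbourhood clipped at borders).
static void rowExtreme(const NumericMatrix& src, NumericMatrix& dst, int half,
                       bool takeMin) {
  const int nr = src.nrow(), nc = src.ncol();
  for (int i = 0; i < nr; ++i) {
    std::deque<int> q; // column indices, values monotone
    int lead = 0;
    for (int j = 0; j < nc; ++j) {
      // advance window right edge to j + half
      for (; lead <= j + half && lead < nc; ++lead) {
        double v = src(i, lead);
        while (!q.empty() &&
               (takeMin ? src(i, q.back()) >= v : src(i, q.back()) <= v))
          q.pop_back();
        q.push_back(lead);
      }
      while (!q.empty() && q.front() < j - half) q.pop_front();
      dst(i, j) = src(i, q.front());
    }
  }
}

static NumericMatrix discExtreme(const NumericMatrix& img, int radius,
                                 bool takeMin) {
  const int nr = img.nrow(), nc = img.ncol();
  // disc rows: vertical offset dy has horizontal half-width floor(sqrt(r^2-dy^2))
  std::map<int, NumericMatrix> byHalf;
  std::vector<int> half(2 * radius + 1);
  for (int dy = -radius; dy <= radius; ++dy) {
    int h = (int)std::floor(std::sqrt((double)radius * radius - (double)dy * dy));
    half[dy + radius] = h;
    if (byHalf.find(h) == byHalf.end()) {
      NumericMatrix f(nr, nc);
      rowExtreme(img, f, h, takeMin);
      byHalf.insert(std::make_pair(h, f));
    }
  }
  NumericMatrix out(nr, nc);
  const double init = takeMin ? R_PosInf : R_NegInf;
  std::fill(out.begin(), out.end(), init);
  for (int dy = -radius; dy <= radius; ++dy) {
    const NumericMatrix& f = byHalf.find(half[dy + radius])->second;
    for (int j = 0; j < nc; ++j) {
      for (int i = std::max(0, -dy); i < std::min(nr, nr - dy); ++i) {
        double v = f(i + dy, j);
        if (takeMin ? v < out(i, j) : v > out(i, j)) out(i, j) = v;
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".discErode", rng = false)]]
NumericMatrix discErode(NumericMatrix img, int radius) {
  if (radius < 0) stop("radius must be >= 0");
  if (radius == 0) return clone(img);
  return discExtreme(img, radius, true);
}

// [[Rcpp::export(name = ".discDilate", rng = false)]]
NumericMatrix discDilate(NumericMatrix img, int radius) {
  if (radius < 0) stop("radius must be >= 0");
  if (radius == 0) return clone(img);
  return discExtreme(img, radius, false);
}

// 8-connected component labelling; labels assigned in column-major
// first-encounter order, background = 0.
// [[Rcpp::export(name = ".label8", rng = false)]]
IntegerMatrix label8(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      int cur = 0;
      // previously scanned neighbours in column-major order
      const int di[4] = {-1, -1, 0, 1};
      const int dj[4] = {0, -1, -1, -1};
      for (int k = 0; k < 4; ++k) {
        int ii = i + di[k], jj = j + dj[k];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        int l = lab(ii, jj);
        if (l > 0) {
          if (cur == 0) cur = l; else unite(cur, l);
        }
      }
      if (cur == 0) { cur = ++next; parent.push_back(cur); }
      lab(i, j) = cur;
    }
  }
  // flatten + renumber consecutively in first-encounter order
  std::vector<int> newlab(next + 1, 0);
  int nfinal = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (lab(i, j) > 0) {
        int r = find(lab(i, j));
        if (newlab[r] == 0) newlab[r] = ++nfinal;
        lab(i, j) = newlab[r];
      }
  return lab;
}
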