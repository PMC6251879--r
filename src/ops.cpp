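#include <Rcpp.h>
#include <queue>
#include <algorithm>
using namespace Rcpp;

// Half-sample symmetric reflection: index -1 maps to 0, n maps to n-1.
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// 2-D correlation with reflect padding. Kernels here are either symmetric
// (LoG) or used only through a magnitude (Sobel), so the correlation /
// convolution distinction never matters downstream.
// [[Rcpp::export]]
NumericMatrix cpp_conv2_reflect(const NumericMatrix& img, const NumericMatrix& kern) {
  const int nr = img.nrow(), nc = img.ncol();
  const int kr = kern.nrow(), kc = kern.ncol();
  const int hr = kr / 2, hc = kc / 2;
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0;
      for (int j = 0; j < kc; ++j) {
        const int cc = reflect_idx(c + j - hc, nc);
        for (int i = 0; i < kr; ++i) {
          const int rr = reflect_idx(r + i - hr, nr);
          acc += img(rr, cc) * kern(i, j);
        }
      }
      out(r, c) = acc;
    }
  }
  return out;
}

// Flat erosion/dilation with a disc structuring element (all offsets within
// Euclidean distance diameter/2 of the centre), clipped at image borders:
// the extremum is taken over the intersection of the disc with the image.
// [[Rcpp::export]]
NumericMatrix cpp_morph_disc(const NumericMatrix& img, double diameter, bool erode) {
  const int nr = img.nrow(), nc = img.ncol();
  const double rad = diameter / 2.0, r2 = rad * rad;
  const int R = (int)std::floor(rad);
  std::vector<int> dr, dc;
  for (int i = -R; i <= R; ++i)
    for (int j = -R; j <= R; ++j)
      if ((double)(i * i + j * j) <= r2) { dr.push_back(i); dc.push_back(j); }
  const int K = (int)dr.size();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double best = erode ? R_PosInf : R_NegInf;
      for (int k = 0; k < K; ++k) {
        const int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        const double v = img(rr, cc);
        if (erode ? (v < best) : (v > best)) best = v;
      }
      out(r, c) = best;
    }
  }
  return out;
}

// Local maxima within a mask: pixel p is reported iff no in-mask pixel q with
// 0 < dist(p,q) <= radius has a larger value, no equal-valued such q
// precedes p in (row, col) lexicographic order (plateau tie-break), and at
// least one such q is strictly smaller (a constant region has no maximum).
// Returns an n x 2 matrix of 1-based (row, col).
// [[Rcpp::export]]
IntegerMatrix cpp_local_maxima(const NumericMatrix& img, const LogicalMatrix& mask,
                               double radius) {
  const int nr = img.nrow(), nc = img.ncol();
  const double r2 = radius * radius;
  const int R = (int)std::floor(radius);
  std::vector<int> dr, dc;
  for (int i = -R; i <= R; ++i)
    for (int j = -R; j <= R; ++j)
      if ((i != 0 || j != 0) && (double)(i * i + j * j) <= r2) {
        dr.push_back(i); dc.push_back(j);
      }
  const int K = (int)dr.size();
  std::vector<int> out_r, out_c;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      const double v = img(r, c);
      bool keep = true, any_lower = false;
      for (int k = 0; k < K; ++k) {
        const int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc || !mask(rr, cc)) continue;
        const double u = img(rr, cc);
        if (u > v || (u == v && (rr < r || (rr == r && cc < c)))) { keep = false; break; }
        if (u < v) any_lower = true;
      }
      if (keep && any_lower) { out_r.push_back(r + 1); out_c.push_back(c + 1); }
    }
  }
  IntegerMatrix out((int)out_r.size(), 2);
  for (int i = 0; i < (int)out_r.size(); ++i) { out(i, 0) = out_r[i]; out(i, 1) = out_c[i]; }
  return out;
}

// Area growing from seed maxima. Seeds are processed in order of decreasing
// seed intensity (ties to smaller (row, col)); each grows an 8-connected
// region over unclaimed in-mask pixels with intensity >= frac * seed
// intensity and >= floor_val. A seed already claimed by a brighter region
// yields an empty set. Returns a list (same order as input seeds) of n x 2
// 1-based (row, col) matrices.
// [[Rcpp::export]]
List cpp_grow_objects(const NumericMatrix& img, const LogicalMatrix& mask,
                      const IntegerMatrix& seeds, double frac, double floor_val) {
  const int nr = img.nrow(), nc = img.ncol();
  const int ns = seeds.nrow();
  std::vector<int> order(ns);
  for (int i = 0; i < ns; ++i) order[i] = i;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    const double va = img(seeds(a, 0) - 1, seeds(a, 1) - 1);
    const double vb = img(seeds(b, 0) - 1, seeds(b, 1) - 1);
    if (va != vb) return va > vb;
    if (seeds(a, 0) != seeds(b, 0)) return seeds(a, 0) < seeds(b, 0);
    return seeds(a, 1) < seeds(b, 1);
  });
  std::vector<int> claim((size_t)nr * nc, -1);
  List out(ns);
  const int d8r[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int d8c[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  for (int oi = 0; oi < ns; ++oi) {
    const int si = order[oi];
    const int sr = seeds(si, 0) - 1, sc = seeds(si, 1) - 1;
    std::vector<int> px_r, px_c;
    if (claim[(size_t)sc * nr + sr] < 0 && mask(sr, sc)) {
      const double lim = std::max(frac * img(sr, sc), floor_val);
      if (img(sr, sc) >= lim) {
        std::queue<std::pair<int,int> > q;
        claim[(size_t)sc * nr + sr] = si;
        q.push(std::make_pair(sr, sc));
        while (!q.empty()) {
          const int r = q.front().first, c = q.front().second; q.pop();
          px_r.push_back(r + 1); px_c.push_back(c + 1);
          for (int k = 0; k < 8; ++k) {
            const int rr = r + d8r[k], cc = c + d8c[k];
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (!mask(rr, cc)) continue;
            if (claim[(size_t)cc * nr + rr] >= 0) continue;
            if (img(rr, cc) < lim) continue;
            claim[(size_t)cc * nr + rr] = si;
            q.push(std::make_pair(rr, cc));
          }
        }
      }
    }
    IntegerMatrix m((int)px_r.size(), 2);
    for (int i = 0; i < (int)px_r.size(); ++i) { m(i, 0) = px_r[i]; m(i, 1) = px_c[i]; }
    out[si] = m;
  }
  return out;
}
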