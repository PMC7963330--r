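// Voxel-level primitives shared by the imaging, morphometry and calcium-event
// stages. Arrays arrive as R arrays in column-major order with dim = (d1,d2,d3);
// the neighbourhood conventions (26-connectivity for foreground, 6 for the
// background complement in the thinning test) follow the package defaults.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline int lin(int a, int b, int c, int d1, int d2) {
  return a + d1 * (b + d2 * c);
}

// 26-connected component labelling by BFS. Returns 0 for background.
// [[Rcpp::export]]
IntegerVector cpp_label_3d(LogicalVector mask, IntegerVector dim) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  IntegerVector lab(n, 0);
  int cur = 0;
  std::vector<int> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    stack.clear();
    stack.push_back((int)s);
    lab[s] = cur;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      int a = v % d1, rest = v / d1;
      int b = rest % d2, c = rest / d2;
      for (int dc = -1; dc <= 1; ++dc) {
        int cc = c + dc; if (cc < 0 || cc >= d3) continue;
        for (int db = -1; db <= 1; ++db) {
          int bb = b + db; if (bb < 0 || bb >= d2) continue;
          for (int da = -1; da <= 1; ++da) {
            int aa = a + da; if (aa < 0 || aa >= d1) continue;
            int w = lin(aa, bb, cc, d1, d2);
            if (mask[w] && !lab[w]) { lab[w] = cur; stack.push_back(w); }
          }
        }
      }
    }
  }
  return lab;
}

// Hysteresis: BFS through voxels >= lo seeded at voxels >= hi (26-connectivity).
// [[Rcpp::export]]
LogicalVector cpp_hysteresis_3d(NumericVector img, IntegerVector dim,
                                double lo, double hi) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  LogicalVector out(n, false);
  std::vector<int> stack;
  for (R_xlen_t s = 0; s < n; ++s)
    if (img[s] >= hi && !out[s]) { out[s] = true; stack.push_back((int)s); }
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    int a = v % d1, rest = v / d1;
    int b = rest % d2, c = rest / d2;
    for (int dc = -1; dc <= 1; ++dc) {
      int cc = c + dc; if (cc < 0 || cc >= d3) continue;
      for (int db = -1; db <= 1; ++db) {
        int bb = b + db; if (bb < 0 || bb >= d2) continue;
        for (int da = -1; da <= 1; ++da) {
          int aa = a + da; if (aa < 0 || aa >= d1) continue;
          int w = lin(aa, bb, cc, d1, d2);
          if (!out[w] && img[w] >= lo) { out[w] = true; stack.push_back(w); }
        }
      }
    }
  }
  return out;
}

// ---- topology helpers for thinning (work on a 3x3x3 local cube) ------------

// number of 26-connected foreground components in the 26-neighbourhood
static int n26_components(const int nb[27]) {
  bool seen[27] = {false};
  int comps = 0;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || seen[i]) continue;
    ++comps;
    std::vector<int> st; st.push_back(i); seen[i] = true;
    while (!st.empty()) {
      int v = st.back(); st.pop_back();
      int a = v % 3, b = (v / 3) % 3, c = v / 9;
      for (int dc = -1; dc <= 1; ++dc) for (int db = -1; db <= 1; ++db)
        for (int da = -1; da <= 1; ++da) {
          int aa = a + da, bb = b + db, cc = c + dc;
          if (aa < 0 || aa > 2 || bb < 0 || bb > 2 || cc < 0 || cc > 2) continue;
          int w = aa + 3 * bb + 9 * cc;
          if (w == 13 || !nb[w] || seen[w]) continue;
          seen[w] = true; st.push_back(w);
        }
    }
  }
  return comps;
}

// number of 6-connected background components in the 18-neighbourhood that
// are 6-adjacent to the centre (paths restricted to the 18-neighbourhood)
static int n6_bg_components(const int nb[27]) {
  auto manh = [](int i) {
    int a = i % 3 - 1, b = (i / 3) % 3 - 1, c = i / 9 - 1;
    return std::abs(a) + std::abs(b) + std::abs(c);
  };
  bool seen[27] = {false};
  int comps = 0;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || nb[i] || seen[i]) continue;
    if (manh(i) != 1) continue;            // start only from face neighbours
    ++comps;
    std::vector<int> st; st.push_back(i); seen[i] = true;
    while (!st.empty()) {
      int v = st.back(); st.pop_back();
      int a = v % 3, b = (v / 3) % 3, c = v / 9;
      const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int k = 0; k < 6; ++k) {
        int aa = a + off[k][0], bb = b + off[k][1], cc = c + off[k][2];
        if (aa < 0 || aa > 2 || bb < 0 || bb > 2 || cc < 0 || cc > 2) continue;
        int w = aa + 3 * bb + 9 * cc;
        if (w == 13 || nb[w] || seen[w]) continue;
        if (manh(w) > 2) continue;          // stay inside the 18-neighbourhood
        seen[w] = true; st.push_back(w);
      }
    }
  }
  return comps;
}

static void fill_neighbourhood(const LogicalVector &mask, int a, int b, int c,
                               int d1, int d2, int d3, int nb[27]) {
  for (int dc = -1; dc <= 1; ++dc) for (int db = -1; db <= 1; ++db)
    for (int da = -1; da <= 1; ++da) {
      int aa = a + da, bb = b + db, cc = c + dc;
      int idx = (da + 1) + 3 * (db + 1) + 9 * (dc + 1);
      if (aa < 0 || aa >= d1 || bb < 0 || bb >= d2 || cc < 0 || cc >= d3)
        nb[idx] = 0;
      else
        nb[idx] = mask[lin(aa, bb, cc, d1, d2)] ? 1 : 0;
    }
}

static inline int n_fg_neighbours(const int nb[27]) {
  int s = 0;
  for (int i = 0; i < 27; ++i) if (i != 13 && nb[i]) ++s;
  return s;
}

static bool is_simple(const int nb[27]) {
  return n26_components(nb) == 1 && n6_bg_components(nb) == 1;
}

// Curve thinning to a medial-axis skeleton: directional sub-iterations delete
// simple, non-endpoint border voxels until stable. Endpoints (<=1 foreground
// neighbour) are preserved so branch tips survive.
// [[Rcpp::export]]
LogicalVector cpp_skeletonize_3d(LogicalVector mask_in, IntegerVector dim) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  LogicalVector mask = clone(mask_in);
  const int dirs[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  int nb[27];
  bool changed = true;
  std::vector<int> cand;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int c = 0; c < d3; ++c) for (int b = 0; b < d2; ++b)
        for (int a = 0; a < d1; ++a) {
          int v = lin(a, b, c, d1, d2);
          if (!mask[v]) continue;
          int aa = a + dirs[d][0], bb = b + dirs[d][1], cc = c + dirs[d][2];
          bool border = (aa < 0 || aa >= d1 || bb < 0 || bb >= d2 ||
                         cc < 0 || cc >= d3) ||
                        !mask[lin(aa, bb, cc, d1, d2)];
          if (!border) continue;
          fill_neighbourhood(mask, a, b, c, d1, d2, d3, nb);
          if (n_fg_neighbours(nb) <= 1) continue;    // endpoint
          if (is_simple(nb)) cand.push_back(v);
        }
      // sequential re-check: earlier deletions may invalidate later candidates
      for (size_t i = 0; i < cand.size(); ++i) {
        int v = cand[i];
        int a = v % d1, rest = v / d1;
        int b = rest % d2, c = rest / d2;
        fill_neighbourhood(mask, a, b, c, d1, d2, d3, nb);
        if (n_fg_neighbours(nb) <= 1) continue;
        if (is_simple(nb)) { mask[v] = false; changed = true; }
      }
    }
  }
  return mask;
}

// Rolling quantile per column, centred window truncated at the edges.
// x is (time x pixels); used for the rolling-percentile F0 baseline.
// [[Rcpp::export]]
NumericMatrix cpp_rolling_quantile(NumericMatrix x, int window, double prob) {
  int T = x.nrow(), P = x.ncol();
  NumericMatrix out(T, P);
  int h = window / 2;
  std::vector<double> buf;
  for (int p = 0; p < P; ++p) {
    for (int t = 0; t < T; ++t) {
      int lo = std::max(0, t - h), hi = std::min(T - 1, t + h);
      int m = hi - lo + 1;
      buf.assign(&x(lo, p), &x(lo, p) + m);
      double pos = prob * (m - 1);
      int k = (int)std::floor(pos);
      double frac = pos - k;
      std::nth_element(buf.begin(), buf.begin() + k, buf.end());
      double v1 = buf[k];
      double v2 = v1;
      if (frac > 0 && k + 1 < m) {
        std::nth_element(buf.begin() + k + 1, buf.begin() + k + 1, buf.end());
        v2 = buf[k + 1];
      }
      out(t, p) = v1 + frac * (v2 - v1);
    }
  }
  return out;
}

// ---- separable Gaussian blur ------------------------------------------------

static void gauss_1d_inplace(std::vector<double> &line, double sigma) {
  if (sigma <= 0) return;
  int r = (int)std::ceil(3.0 * sigma);
  int n = (int)line.size();
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (auto &v : k) v /= s;
  std::vector<double> out(n);
  for (int i = 0; i < n; ++i) {
    double acc = 0;
    for (int j = -r; j <= r; ++j) {
      int idx = i + j;
      // reflect (repeatedly: the kernel may be wider than the line)
      while (idx < 0 || idx >= n) {
        if (idx < 0) idx = -idx - 1;
        if (idx >= n) idx = 2 * n - idx - 1;
      }
      acc += k[j + r] * line[idx];
    }
    out[i] = acc;
  }
  line.swap(out);
}

// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector img, IntegerVector dim,
                          double s1, double s2, double s3) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  NumericVector out = clone(img);
  std::vector<double> line;
  if (s1 > 0) {
    line.resize(d1);
    for (int c = 0; c < d3; ++c) for (int b = 0; b < d2; ++b) {
      for (int a = 0; a < d1; ++a) line[a] = out[lin(a, b, c, d1, d2)];
      gauss_1d_inplace(line, s1);
      for (int a = 0; a < d1; ++a) out[lin(a, b, c, d1, d2)] = line[a];
    }
  }
  if (s2 > 0) {
    line.resize(d2);
    for (int c = 0; c < d3; ++c) for (int a = 0; a < d1; ++a) {
      for (int b = 0; b < d2; ++b) line[b] = out[lin(a, b, c, d1, d2)];
      gauss_1d_inplace(line, s2);
      for (int b = 0; b < d2; ++b) out[lin(a, b, c, d1, d2)] = line[b];
    }
  }
  if (s3 > 0) {
    line.resize(d3);
    for (int b = 0; b < d2; ++b) for (int a = 0; a < d1; ++a) {
      for (int c = 0; c < d3; ++c) line[c] = out[lin(a, b, c, d1, d2)];
      gauss_1d_inplace(line, s3);
      for (int c = 0; c < d3; ++c) out[lin(a, b, c, d1, d2)] = line[c];
    }
  }
  return out;
}

// ---- 2D coherence-enhancing diffusion (Weickert-type, explicit scheme) ------

static void gauss_mat(std::vector<double> &m, int nr, int nc, double sigma) {
  if (sigma <= 0) return;
  std::vector<double> line;
  line.resize(nr);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) line[r] = m[r + nr * c];
    gauss_1d_inplace(line, sigma);
    for (int r = 0; r < nr; ++r) m[r + nr * c] = line[r];
  }
  line.resize(nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) line[c] = m[r + nr * c];
    gauss_1d_inplace(line, sigma);
    for (int c = 0; c < nc; ++c) m[r + nr * c] = line[c];
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_ced2d(NumericMatrix u_in, int iters, double tau,
                        double sigma, double rho, double alpha, double cpar) {
  int nr = u_in.nrow(), nc = u_in.ncol();
  std::vector<double> u(u_in.begin(), u_in.end());
  int n = nr * nc;
  std::vector<double> us(n), ux(n), uy(n), j11(n), j12(n), j22(n);
  std::vector<double> D11(n), D12(n), D22(n), f1(n), f2(n);
  auto at = [&](std::vector<double> &m, int r, int c) -> double {
    if (r < 0) r = 0; if (r >= nr) r = nr - 1;
    if (c < 0) c = 0; if (c >= nc) c = nc - 1;
    return m[r + nr * c];
  };
  // the steering field is computed once from the pre-smoothed input and
  // kept frozen across iterations; only the cheap diffusion steps repeat
  {
    us = u;
    gauss_mat(us, nr, nc, sigma);
    for (int c = 0; c < nc; ++c) for (int r = 0; r < nr; ++r) {
      double gx = 0.5 * (at(us, r + 1, c) - at(us, r - 1, c));
      double gy = 0.5 * (at(us, r, c + 1) - at(us, r, c - 1));
      int i = r + nr * c;
      ux[i] = gx; uy[i] = gy;
      j11[i] = gx * gx; j12[i] = gx * gy; j22[i] = gy * gy;
    }
    gauss_mat(j11, nr, nc, rho);
    gauss_mat(j12, nr, nc, rho);
    gauss_mat(j22, nr, nc, rho);
    // contrast scale: if not given, use an upper-quantile of the coherence
    double C = cpar;
    if (C <= 0) {
      std::vector<double> kap(n);
      for (int i = 0; i < n; ++i) {
        double df = j11[i] - j22[i];
        double disc = std::sqrt(df * df + 4 * j12[i] * j12[i]);
        kap[i] = disc * disc;
      }
      std::vector<double> tmp = kap;
      size_t q = (size_t)(0.90 * (n - 1));
      std::nth_element(tmp.begin(), tmp.begin() + q, tmp.end());
      C = std::max(tmp[q], 1e-12);
    }
    for (int i = 0; i < n; ++i) {
      double tr = j11[i] + j22[i];
      double df = j11[i] - j22[i];
      double disc = std::sqrt(df * df + 4 * j12[i] * j12[i]);
      double kappa = disc * disc;
      double l_along = alpha + (1 - alpha) * std::exp(-C / std::max(kappa, 1e-300));
      double l_across = alpha;
      // dominant eigenvector (gradient direction) angle
      double theta = 0.5 * std::atan2(2 * j12[i], df);
      double c1 = std::cos(theta), s1v = std::sin(theta);
      // v1 = gradient direction gets l_across; v2 (coherence) gets l_along
      D11[i] = l_across * c1 * c1 + l_along * s1v * s1v;
      D22[i] = l_across * s1v * s1v + l_along * c1 * c1;
      D12[i] = (l_across - l_along) * c1 * s1v;
      (void)tr;
    }
  }
  for (int it = 0; it < iters; ++it) {
    // isotropic floor handled by a 5-point Laplacian (damps checkerboard
    // modes that a central-difference divergence leaves untouched); the
    // anisotropic excess (D - alpha I) goes through central differences
    for (int c = 0; c < nc; ++c) for (int r = 0; r < nr; ++r) {
      int i = r + nr * c;
      double gx = 0.5 * (at(u, r + 1, c) - at(u, r - 1, c));
      double gy = 0.5 * (at(u, r, c + 1) - at(u, r, c - 1));
      f1[i] = (D11[i] - alpha) * gx + D12[i] * gy;
      f2[i] = D12[i] * gx + (D22[i] - alpha) * gy;
    }
    std::vector<double> unew = u;
    for (int c = 0; c < nc; ++c) for (int r = 0; r < nr; ++r) {
      int i = r + nr * c;
      double div = 0.5 * (at(f1, r + 1, c) - at(f1, r - 1, c)) +
                   0.5 * (at(f2, r, c + 1) - at(f2, r, c - 1));
      double lap = at(u, r + 1, c) + at(u, r - 1, c) +
                   at(u, r, c + 1) + at(u, r, c - 1) - 4 * u[i];
      unew[i] = u[i] + tau * (div + alpha * lap);
    }
    u.swap(unew);
  }
  NumericMatrix out(nr, nc);
  std::copy(u.begin(), u.end(), out.begin());
  return out;
}

// adjacency edges among flagged voxels (26-connectivity): returns a 2-column
// matrix of 1-based indices into the flagged-voxel list
// [[Rcpp::export]]
IntegerMatrix cpp_flag_edges(LogicalVector mask, IntegerVector dim) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  std::vector<int> id(n, 0);
  int cnt = 0;
  for (R_xlen_t i = 0; i < n; ++i) if (mask[i]) id[i] = ++cnt;
  std::vector<int> from, to;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s]) continue;
    int a = s % d1, rest = (int)(s / d1);
    int b = rest % d2, c = rest / d2;
    for (int dc = -1; dc <= 1; ++dc) {
      int cc = c + dc; if (cc < 0 || cc >= d3) continue;
      for (int db = -1; db <= 1; ++db) {
        int bb = b + db; if (bb < 0 || bb >= d2) continue;
        for (int da = -1; da <= 1; ++da) {
          int aa = a + da; if (aa < 0 || aa >= d1) continue;
          R_xlen_t w = lin(aa, bb, cc, d1, d2);
          if ((R_xlen_t)w <= s || !mask[w]) continue;
          from.push_back(id[s]);
          to.push_back(id[w]);
        }
      }
    }
  }
  IntegerMatrix out(from.size(), 2);
  for (size_t i = 0; i < from.size(); ++i) {
    out(i, 0) = from[i];
    out(i, 1) = to[i];
  }
  return out;
}
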