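#include <Rcpp.h>
#include <queue>
#include <limits>
using namespace Rcpp;

// ---- im2col / col2im (2D) --------------------------------------------------
// x: (H, W, C) column-major; output rows index (oh, ow) = oh + outH*ow,
// columns index (i, j, c) = i + kh*(j + kw*c). Zero padding, stride 1.

// [[Rcpp::export]]
NumericMatrix cpp_im2col2d(NumericVector x, int H, int W, int C,
                           int kh, int kw, int ph, int pw) {
  int outH = H + 2 * ph - kh + 1;
  int outW = W + 2 * pw - kw + 1;
  NumericMatrix out(outH * outW, kh * kw * C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int col = i + kh * (j + kw * c);
        for (int ow = 0; ow < outW; ++ow) {
          int w = ow + j - pw;
          if (w < 0 || w >= W) continue;
          for (int oh = 0; oh < outH; ++oh) {
            int h = oh + i - ph;
            if (h < 0 || h >= H) continue;
            out(oh + outH * ow, col) = x[h + H * (w + W * c)];
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_col2im2d(NumericMatrix cols, int H, int W, int C,
                           int kh, int kw, int ph, int pw) {
  int outH = H + 2 * ph - kh + 1;
  int outW = W + 2 * pw - kw + 1;
  NumericVector x(H * W * C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int col = i + kh * (j + kw * c);
        for (int ow = 0; ow < outW; ++ow) {
          int w = ow + j - pw;
          if (w < 0 || w >= W) continue;
          for (int oh = 0; oh < outH; ++oh) {
            int h = oh + i - ph;
            if (h < 0 || h >= H) continue;
            x[h + H * (w + W * c)] += cols(oh + outH * ow, col);
          }
        }
      }
    }
  }
  return x;
}

// ---- im2col / col2im (3D) --------------------------------------------------
// x: (D1, D2, D3, C) column-major; cubic kernel k, symmetric padding p.

// [[Rcpp::export]]
NumericMatrix cpp_im2col3d(NumericVector x, int D1, int D2, int D3, int C,
                           int k, int p) {
  int o1 = D1 + 2 * p - k + 1, o2 = D2 + 2 * p - k + 1, o3 = D3 + 2 * p - k + 1;
  NumericMatrix out((double)o1 * o2 * o3, k * k * k * C);
  for (int c = 0; c < C; ++c)
    for (int k3 = 0; k3 < k; ++k3)
      for (int k2 = 0; k2 < k; ++k2)
        for (int k1 = 0; k1 < k; ++k1) {
          int col = k1 + k * (k2 + k * (k3 + k * c));
          for (int z = 0; z < o3; ++z) {
            int z0 = z + k3 - p; if (z0 < 0 || z0 >= D3) continue;
            for (int y = 0; y < o2; ++y) {
              int y0 = y + k2 - p; if (y0 < 0 || y0 >= D2) continue;
              for (int xx = 0; xx < o1; ++xx) {
                int x0 = xx + k1 - p; if (x0 < 0 || x0 >= D1) continue;
                out(xx + o1 * (y + o2 * z), col) =
                  x[x0 + D1 * (y0 + D2 * ((double)z0 + D3 * c))];
              }
            }
          }
        }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_col2im3d(NumericMatrix cols, int D1, int D2, int D3, int C,
                           int k, int p) {
  int o1 = D1 + 2 * p - k + 1, o2 = D2 + 2 * p - k + 1, o3 = D3 + 2 * p - k + 1;
  NumericVector x((double)D1 * D2 * D3 * C);
  for (int c = 0; c < C; ++c)
    for (int k3 = 0; k3 < k; ++k3)
      for (int k2 = 0; k2 < k; ++k2)
        for (int k1 = 0; k1 < k; ++k1) {
          int col = k1 + k * (k2 + k * (k3 + k * c));
          for (int z = 0; z < o3; ++z) {
            int z0 = z + k3 - p; if (z0 < 0 || z0 >= D3) continue;
            for (int y = 0; y < o2; ++y) {
              int y0 = y + k2 - p; if (y0 < 0 || y0 >= D2) continue;
              for (int xx = 0; xx < o1; ++xx) {
                int x0 = xx + k1 - p; if (x0 < 0 || x0 >= D1) continue;
                x[x0 + D1 * (y0 + D2 * ((double)z0 + D3 * c))] +=
                  cols(xx + o1 * (y + o2 * z), col);
              }
            }
          }
        }
  return x;
}

// ---- 2x2(x2) max pooling with stored argmax indices ------------------------

// [[Rcpp::export]]
List cpp_maxpool2d(NumericVector x, int H, int W, int C) {
  int h = H / 2, w = W / 2;
  NumericVector out(h * w * C);
  IntegerVector idx(h * w * C);  // 0-based linear index into x
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i) {
        double best = -std::numeric_limits<double>::infinity();
        int bi = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            int lin = (2 * i + di) + H * ((2 * j + dj) + W * c);
            if (x[lin] > best) { best = x[lin]; bi = lin; }
          }
        out[i + h * (j + w * c)] = best;
        idx[i + h * (j + w * c)] = bi;
      }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxunpool2d(NumericVector g, IntegerVector idx, int n_out) {
  NumericVector x(n_out);
  for (int i = 0; i < g.size(); ++i) x[idx[i]] += g[i];
  return x;
}

// [[Rcpp::export]]
List cpp_maxpool3d(NumericVector x, int D1, int D2, int D3, int C) {
  int a = D1 / 2, b = D2 / 2, d = D3 / 2;
  NumericVector out((double)a * b * d * C);
  IntegerVector idx((double)a * b * d * C);
  for (int c = 0; c < C; ++c)
    for (int z = 0; z < d; ++z)
      for (int y = 0; y < b; ++y)
        for (int i = 0; i < a; ++i) {
          double best = -std::numeric_limits<double>::infinity();
          int bi = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                int lin = (2 * i + dx) + D1 * ((2 * y + dy) +
                          D2 * ((2 * z + dz) + D3 * c));
                if (x[lin] > best) { best = x[lin]; bi = lin; }
              }
          int o = i + a * (y + b * (z + d * c));
          out[o] = best; idx[o] = bi;
        }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// ---- exact Euclidean distance transform (Felzenszwalb-Huttenlocher) --------
// Squared distance to the nearest TRUE voxel, per-axis weights (e.g. voxel
// spacing in mm, or 1/radius for ellipsoidal structuring elements).

static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &zb, double w2) {
  int n = (int)f.size();
  d.assign(n, 0.0);
  int kk = 0;
  v.assign(n, 0);
  zb.assign(n + 1, 0.0);
  zb[0] = -std::numeric_limits<double>::infinity();
  zb[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + w2 * q * q) - (f[v[kk]] + w2 * v[kk] * v[kk])) /
          (2.0 * w2 * (q - v[kk]));
      if (s <= zb[kk]) { --kk; } else break;
    }
    ++kk;
    v[kk] = q;
    zb[kk] = s;
    zb[kk + 1] = std::numeric_limits<double>::infinity();
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[kk + 1] < q) ++kk;
    d[q] = w2 * (q - v[kk]) * (q - v[kk]) + f[v[kk]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dims,
                         NumericVector w) {
  int nd = dims.size();
  int D1 = dims[0], D2 = nd > 1 ? dims[1] : 1, D3 = nd > 2 ? dims[2] : 1;
  double BIG = 1e30;
  NumericVector f((double)D1 * D2 * D3);
  for (R_xlen_t i = 0; i < f.size(); ++i) f[i] = mask[i] ? 0.0 : BIG;
  std::vector<double> line, dline, zb;
  std::vector<int> v;
  // axis 1
  line.resize(D1);
  for (int z = 0; z < D3; ++z)
    for (int y = 0; y < D2; ++y) {
      for (int i = 0; i < D1; ++i) line[i] = f[i + D1 * (y + (double)D2 * z)];
      dt1d(line, dline, v, zb, w[0] * w[0]);
      for (int i = 0; i < D1; ++i) f[i + D1 * (y + (double)D2 * z)] = dline[i];
    }
  // axis 2
  if (D2 > 1) {
    line.resize(D2);
    for (int z = 0; z < D3; ++z)
      for (int i = 0; i < D1; ++i) {
        for (int y = 0; y < D2; ++y) line[y] = f[i + D1 * (y + (double)D2 * z)];
        dt1d(line, dline, v, zb, w[1] * w[1]);
        for (int y = 0; y < D2; ++y) f[i + D1 * (y + (double)D2 * z)] = dline[y];
      }
  }
  // axis 3
  if (D3 > 1) {
    line.resize(D3);
    for (int y = 0; y < D2; ++y)
      for (int i = 0; i < D1; ++i) {
        for (int z = 0; z < D3; ++z) line[z] = f[i + D1 * (y + (double)D2 * z)];
        dt1d(line, dline, v, zb, w[2] * w[2]);
        for (int z = 0; z < D3; ++z) f[i + D1 * (y + (double)D2 * z)] = dline[z];
      }
  }
  return f;
}

// ---- connected component labeling ------------------------------------------
// Labels assigned in raster-scan order of each component's first voxel, so
// equal-size ties can be broken deterministically by label index.
// connectivity: 6 = faces only, 26 = faces+edges+corners (2D inputs use the
// same codes with D3 = 1, giving 4- and 8-connectivity).

// [[Rcpp::export]]
IntegerVector cpp_label(LogicalVector mask, IntegerVector dims,
                        int connectivity) {
  int nd = dims.size();
  int D1 = dims[0], D2 = nd > 1 ? dims[1] : 1, D3 = nd > 2 ? dims[2] : 1;
  R_xlen_t n = (R_xlen_t)D1 * D2 * D3;
  IntegerVector lab(n);
  std::vector<std::array<int, 3>> nb;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int nz = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (nz == 0) continue;
        if (connectivity == 6 && nz > 1) continue;
        nb.push_back({dx, dy, dz});
      }
  int cur = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++cur;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t p = q.front(); q.pop();
      int x = (int)(p % D1), y = (int)((p / D1) % D2), z = (int)(p / ((R_xlen_t)D1 * D2));
      for (auto &d : nb) {
        int xx = x + d[0], yy = y + d[1], zz = z + d[2];
        if (xx < 0 || xx >= D1 || yy < 0 || yy >= D2 || zz < 0 || zz >= D3)
          continue;
        R_xlen_t pp = xx + (R_xlen_t)D1 * (yy + (R_xlen_t)D2 * zz);
        if (mask[pp] && !lab[pp]) { lab[pp] = cur; q.push(pp); }
      }
    }
  }
  return lab;
}

// ---- multi-level Otsu -------------------------------------------------------
// Exhaustive maximization of between-class variance over a binned histogram.
// Returns 0-based upper bin index of each class except the last (k indices);
// threshold t means classes split as [..t] | [t+1..].

// [[Rcpp::export]]
IntegerVector cpp_multiotsu(NumericVector hist, int k) {
  int B = hist.size();
  std::vector<double> cw(B), cm(B);  // cumulative weight and weighted mean
  double w = 0, m = 0;
  for (int i = 0; i < B; ++i) {
    w += hist[i];
    m += hist[i] * i;
    cw[i] = w; cm[i] = m;
  }
  auto score = [&](int lo, int hi) {  // class [lo, hi] contribution w*mu^2
    double ww = cw[hi] - (lo > 0 ? cw[lo - 1] : 0.0);
    if (ww <= 0) return 0.0;
    double mm = cm[hi] - (lo > 0 ? cm[lo - 1] : 0.0);
    return mm * mm / ww;
  };
  double best = -1.0;
  IntegerVector res(k);
  if (k == 1) {
    for (int t = 0; t < B - 1; ++t) {
      double s = score(0, t) + score(t + 1, B - 1);
      if (s > best) { best = s; res[0] = t; }
    }
  } else if (k == 2) {
    for (int t1 = 0; t1 < B - 2; ++t1)
      for (int t2 = t1 + 1; t2 < B - 1; ++t2) {
        double s = score(0, t1) + score(t1 + 1, t2) + score(t2 + 1, B - 1);
        if (s > best) { best = s; res[0] = t1; res[1] = t2; }
      }
  } else if (k == 3) {
    for (int t1 = 0; t1 < B - 3; ++t1) {
      double s1 = score(0, t1);
      for (int t2 = t1 + 1; t2 < B - 2; ++t2) {
        double s2 = s1 + score(t1 + 1, t2);
        for (int t3 = t2 + 1; t3 < B - 1; ++t3) {
          double s = s2 + score(t2 + 1, t3) + score(t3 + 1, B - 1);
          if (s > best) { best = s; res[0] = t1; res[1] = t2; res[2] = t3; }
        }
      }
    }
  } else {
    stop("multi-level Otsu implemented for 1-3 thresholds");
  }
  return res;
}
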