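// Low-level image / tensor primitives shared across the package:
// im2col-style convolution support for the small CNNs, separable filtering,
// exact Euclidean distance transform, connected components, 2D thinning,
// constant-offset trilinear resampling, and per-voxel symmetric 3x3
// eigendecomposition. All arrays are column-major (R layout).
#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int outDim(int n, int k, int s) {
  int p = (k - 1) / 2;
  return (n + 2 * p - k) / s + 1;
}

// [[Rcpp::export(name = ".im2col2")]]
arma::mat im2col2(const arma::cube& x, int k, int stride) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int p = (k - 1) / 2;
  const int Ho = outDim(H, k, stride), Wo = outDim(W, k, stride);
  arma::mat out(Ho * Wo, k * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const int col = ki + k * (kj + k * c);
        for (int j = 0; j < Wo; ++j) {
          const int sj = j * stride - p + kj;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int si = i * stride - p + ki;
            if (si < 0 || si >= H) continue;
            out(i + Ho * j, col) = x(si, sj, c);
          }
        }
      }
  return out;
}

// [[Rcpp::export(name = ".col2im2")]]
arma::cube col2im2(const arma::mat& cols, int H, int W, int C, int k,
                   int stride) {
  const int p = (k - 1) / 2;
  const int Ho = outDim(H, k, stride), Wo = outDim(W, k, stride);
  arma::cube out(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const int col = ki + k * (kj + k * c);
        for (int j = 0; j < Wo; ++j) {
          const int sj = j * stride - p + kj;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int si = i * stride - p + ki;
            if (si < 0 || si >= H) continue;
            out(si, sj, c) += cols(i + Ho * j, col);
          }
        }
      }
  return out;
}

// x: 4D array (d1,d2,d3,C) passed as flat vector with dims.
// [[Rcpp::export(name = ".im2col3")]]
arma::mat im2col3(const NumericVector& x, const IntegerVector& dims, int k,
                  int stride) {
  const int D1 = dims[0], D2 = dims[1], D3 = dims[2], C = dims[3];
  const int p = (k - 1) / 2;
  const int O1 = outDim(D1, k, stride), O2 = outDim(D2, k, stride),
            O3 = outDim(D3, k, stride);
  arma::mat out(static_cast<size_t>(O1) * O2 * O3,
                static_cast<size_t>(k) * k * k * C, arma::fill::zeros);
  const double* px = x.begin();
  for (int c = 0; c < C; ++c)
    for (int k3 = 0; k3 < k; ++k3)
      for (int k2 = 0; k2 < k; ++k2)
        for (int k1 = 0; k1 < k; ++k1) {
          const size_t col =
              k1 + static_cast<size_t>(k) * (k2 + k * (k3 + k * c));
          for (int i3 = 0; i3 < O3; ++i3) {
            const int s3 = i3 * stride - p + k3;
            if (s3 < 0 || s3 >= D3) continue;
            for (int i2 = 0; i2 < O2; ++i2) {
              const int s2 = i2 * stride - p + k2;
              if (s2 < 0 || s2 >= D2) continue;
              for (int i1 = 0; i1 < O1; ++i1) {
                const int s1 = i1 * stride - p + k1;
                if (s1 < 0 || s1 >= D1) continue;
                out(i1 + static_cast<size_t>(O1) * (i2 + O2 * i3), col) =
                    px[s1 + static_cast<size_t>(D1) *
                                (s2 + static_cast<size_t>(D2) *
                                          (s3 + static_cast<size_t>(D3) * c))];
              }
            }
          }
        }
  return out;
}

// [[Rcpp::export(name = ".col2im3")]]
NumericVector col2im3(const arma::mat& cols, const IntegerVector& dims, int k,
                      int stride) {
  const int D1 = dims[0], D2 = dims[1], D3 = dims[2], C = dims[3];
  const int p = (k - 1) / 2;
  const int O1 = outDim(D1, k, stride), O2 = outDim(D2, k, stride),
            O3 = outDim(D3, k, stride);
  NumericVector out(static_cast<R_xlen_t>(D1) * D2 * D3 * C);
  out.attr("dim") = dims;
  double* po = out.begin();
  for (int c = 0; c < C; ++c)
    for (int k3 = 0; k3 < k; ++k3)
      for (int k2 = 0; k2 < k; ++k2)
        for (int k1 = 0; k1 < k; ++k1) {
          const size_t col =
              k1 + static_cast<size_t>(k) * (k2 + k * (k3 + k * c));
          for (int i3 = 0; i3 < O3; ++i3) {
            const int s3 = i3 * stride - p + k3;
            if (s3 < 0 || s3 >= D3) continue;
            for (int i2 = 0; i2 < O2; ++i2) {
              const int s2 = i2 * stride - p + k2;
              if (s2 < 0 || s2 >= D2) continue;
              for (int i1 = 0; i1 < O1; ++i1) {
                const int s1 = i1 * stride - p + k1;
                if (s1 < 0 || s1 >= D1) continue;
                po[s1 + static_cast<size_t>(D1) *
                            (s2 + static_cast<size_t>(D2) *
                                      (s3 + static_cast<size_t>(D3) * c))] +=
                    cols(i1 + static_cast<size_t>(O1) * (i2 + O2 * i3), col);
              }
            }
          }
        }
  return out;
}

// 1D convolution along one axis of a (d1,d2,d3) array, replicate padding.
// [[Rcpp::export(name = ".convAxis")]]
NumericVector convAxis(const NumericVector& x, const IntegerVector& dims,
                       const NumericVector& kern, int axis) {
  const int D1 = dims[0], D2 = dims[1], D3 = dims[2];
  const int kl = kern.size(), half = (kl - 1) / 2;
  NumericVector out(x.size());
  out.attr("dim") = dims;
  const double* px = x.begin();
  double* po = out.begin();
  const int n[3] = {D1, D2, D3};
  const size_t strd[3] = {1, static_cast<size_t>(D1),
                          static_cast<size_t>(D1) * D2};
  const int na = n[axis];
  const size_t sa = strd[axis];
  for (int i3 = 0; i3 < D3; ++i3)
    for (int i2 = 0; i2 < D2; ++i2)
      for (int i1 = 0; i1 < D1; ++i1) {
        const int idx[3] = {i1, i2, i3};
        const size_t base = i1 + strd[1] * i2 + strd[2] * i3;
        double acc = 0.0;
        for (int t = 0; t < kl; ++t) {
          int q = idx[axis] + t - half;
          if (q < 0) q = 0;
          if (q >= na) q = na - 1;
          acc += kern[t] * px[base + sa * (q - idx[axis])];
        }
        po[base] = acc;
      }
  return out;
}

// Felzenszwalb-Huttenlocher exact squared EDT, anisotropic spacing.
// Only finite samples enter the lower envelope: infinite parabolas can
// never win and would otherwise corrupt the envelope index.
static void edt1d(const std::vector<double>& f, std::vector<double>& d,
                  double h) {
  const int n = f.size();
  std::vector<int> pos;
  pos.reserve(n);
  for (int i = 0; i < n; ++i)
    if (std::isfinite(f[i])) pos.push_back(i);
  if (pos.empty()) {
    for (int i = 0; i < n; ++i) d[i] = INFINITY;
    return;
  }
  std::vector<int> v(pos.size());
  std::vector<double> z(pos.size() + 1);
  int q = 0;
  v[0] = pos[0];
  z[0] = -INFINITY;
  z[1] = INFINITY;
  const double h2 = h * h;
  for (size_t t = 1; t < pos.size(); ++t) {
    const int i = pos[t];
    double s;
    while (true) {
      s = ((f[i] + h2 * static_cast<double>(i) * i) -
           (f[v[q]] + h2 * static_cast<double>(v[q]) * v[q])) /
          (2.0 * h2 * (i - v[q]));
      if (q > 0 && s <= z[q]) {
        --q;
      } else
        break;
    }
    ++q;
    v[q] = i;
    z[q] = s;
    z[q + 1] = INFINITY;
  }
  q = 0;
  for (int i = 0; i < n; ++i) {
    while (z[q + 1] < i) ++q;
    d[i] = h2 * static_cast<double>(i - v[q]) * (i - v[q]) + f[v[q]];
  }
}

// Distance (in physical units) from each foreground voxel to the nearest
// background voxel. mask: 0/1 array (d1,d2,d3); spacing per axis.
// [[Rcpp::export(name = ".edt3")]]
NumericVector edt3(const NumericVector& mask, const IntegerVector& dims,
                   const NumericVector& spacing) {
  const int D1 = dims[0], D2 = dims[1], D3 = dims[2];
  const size_t N = static_cast<size_t>(D1) * D2 * D3;
  std::vector<double> g(N);
  for (size_t i = 0; i < N; ++i) g[i] = mask[i] > 0 ? INFINITY : 0.0;
  const size_t strd[3] = {1, static_cast<size_t>(D1),
                          static_cast<size_t>(D1) * D2};
  const int n[3] = {D1, D2, D3};
  for (int axis = 0; axis < 3; ++axis) {
    if (n[axis] == 1) continue;
    std::vector<double> f(n[axis]), d(n[axis]);
    const int nb = n[(axis + 1) % 3], nc = n[(axis + 2) % 3];
    const size_t sb = strd[(axis + 1) % 3], sc = strd[(axis + 2) % 3];
    for (int c = 0; c < nc; ++c)
      for (int b = 0; b < nb; ++b) {
        const size_t base = sb * b + sc * c;
        bool allinf = true;
        for (int a = 0; a < n[axis]; ++a) {
          f[a] = g[base + strd[axis] * a];
          if (std::isfinite(f[a])) allinf = false;
        }
        if (allinf) continue;
        edt1d(f, d, spacing[axis]);
        for (int a = 0; a < n[axis]; ++a) g[base + strd[axis] * a] = d[a];
      }
  }
  NumericVector out(N);
  out.attr("dim") = dims;
  for (size_t i = 0; i < N; ++i)
    out[i] = std::isfinite(g[i]) ? std::sqrt(g[i]) : INFINITY;
  return out;
}

// Connected components, 26-connectivity (8-connectivity when a dim is 1).
// [[Rcpp::export(name = ".ccLabel")]]
IntegerVector ccLabel(const LogicalVector& mask, const IntegerVector& dims) {
  const int D1 = dims[0], D2 = dims[1], D3 = dims[2];
  const size_t N = static_cast<size_t>(D1) * D2 * D3;
  IntegerVector lab(N);
  lab.attr("dim") = dims;
  int cur = 0;
  std::queue<size_t> q;
  for (size_t seed = 0; seed < N; ++seed) {
    if (!mask[seed] || lab[seed] != 0) continue;
    ++cur;
    lab[seed] = cur;
    q.push(seed);
    while (!q.empty()) {
      const size_t v = q.front();
      q.pop();
      const int i1 = v % D1, i2 = (v / D1) % D2, i3 = v / (static_cast<size_t>(D1) * D2);
      for (int d3 = -1; d3 <= 1; ++d3)
        for (int d2 = -1; d2 <= 1; ++d2)
          for (int d1 = -1; d1 <= 1; ++d1) {
            if (!d1 && !d2 && !d3) continue;
            const int j1 = i1 + d1, j2 = i2 + d2, j3 = i3 + d3;
            if (j1 < 0 || j1 >= D1 || j2 < 0 || j2 >= D2 || j3 < 0 ||
                j3 >= D3)
              continue;
            const size_t w =
                j1 + static_cast<size_t>(D1) * (j2 + static_cast<size_t>(D2) * j3);
            if (mask[w] && lab[w] == 0) {
              lab[w] = cur;
              q.push(w);
            }
          }
    }
  }
  lab.attr("n") = IntegerVector::create(cur);
  return lab;
}

// Zhang-Suen thinning of a binary matrix.
// [[Rcpp::export(name = ".thin2d")]]
LogicalMatrix thin2d(const LogicalMatrix& img) {
  const int H = img.nrow(), W = img.ncol();
  std::vector<char> a(static_cast<size_t>(H) * W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) a[i + static_cast<size_t>(H) * j] = img(i, j);
  auto at = [&](int i, int j) -> char {
    if (i < 0 || i >= H || j < 0 || j >= W) return 0;
    return a[i + static_cast<size_t>(H) * j];
  };
  bool changed = true;
  std::vector<std::pair<int, int>> del;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      del.clear();
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          if (!at(i, j)) continue;
          // neighbours p2..p9 clockwise from north (row -1)
          const char p2 = at(i - 1, j), p3 = at(i - 1, j + 1), p4 = at(i, j + 1),
                     p5 = at(i + 1, j + 1), p6 = at(i + 1, j),
                     p7 = at(i + 1, j - 1), p8 = at(i, j - 1),
                     p9 = at(i - 1, j - 1);
          const int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = 0;
          const char seq[9] = {p2, p3, p4, p5, p6, p7, p8, p9, p2};
          for (int t = 0; t < 8; ++t)
            if (!seq[t] && seq[t + 1]) ++A;
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          del.emplace_back(i, j);
        }
      for (auto& pr : del) a[pr.first + static_cast<size_t>(H) * pr.second] = 0;
      if (!del.empty()) changed = true;
    }
  }
  LogicalMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) out(i, j) = a[i + static_cast<size_t>(H) * j];
  return out;
}

// Trilinear sampling of vol at (i1+o1, i2+o2, i3+o3); zero outside.
// [[Rcpp::export(name = ".shiftSample")]]
NumericVector shiftSample(const NumericVector& vol, const IntegerVector& dims,
                          double o1, double o2, double o3) {
  const int D1 = dims[0], D2 = dims[1], D3 = dims[2];
  NumericVector out(vol.size());
  out.attr("dim") = dims;
  const double* pv = vol.begin();
  double* po = out.begin();
  auto get = [&](int i, int j, int k) -> double {
    if (i < 0 || i >= D1 || j < 0 || j >= D2 || k < 0 || k >= D3) return 0.0;
    return pv[i + static_cast<size_t>(D1) * (j + static_cast<size_t>(D2) * k)];
  };
  for (int i3 = 0; i3 < D3; ++i3)
    for (int i2 = 0; i2 < D2; ++i2)
      for (int i1 = 0; i1 < D1; ++i1) {
        const double z = i1 + o1, x = i2 + o2, y = i3 + o3;
        const int z0 = std::floor(z), x0 = std::floor(x), y0 = std::floor(y);
        const double fz = z - z0, fx = x - x0, fy = y - y0;
        double acc = 0.0;
        for (int dz = 0; dz <= 1; ++dz)
          for (int dx = 0; dx <= 1; ++dx)
            for (int dy = 0; dy <= 1; ++dy) {
              const double w = (dz ? fz : 1 - fz) * (dx ? fx : 1 - fx) *
                               (dy ? fy : 1 - fy);
              if (w > 0) acc += w * get(z0 + dz, x0 + dx, y0 + dy);
            }
        po[i1 + static_cast<size_t>(D1) * (i2 + static_cast<size_t>(D2) * i3)] =
            acc;
      }
  return out;
}

// Per-voxel eigendecomposition of a symmetric 3x3 matrix field.
// Returns eigenvalues sorted by increasing |lambda| and the eigenvector of
// the smallest-|lambda| eigenvalue (the tube axis for Hessian/OOF fields).
// [[Rcpp::export(name = ".sym3Eigen")]]
List sym3Eigen(const NumericVector& a11, const NumericVector& a22,
               const NumericVector& a33, const NumericVector& a12,
               const NumericVector& a13, const NumericVector& a23) {
  const R_xlen_t N = a11.size();
  NumericVector l1(N), l2(N), l3(N), v1(N), v2(N), v3(N);
  arma::mat33 M;
  arma::vec3 ev;
  arma::mat33 evec;
  for (R_xlen_t i = 0; i < N; ++i) {
    M(0, 0) = a11[i]; M(1, 1) = a22[i]; M(2, 2) = a33[i];
    M(0, 1) = M(1, 0) = a12[i];
    M(0, 2) = M(2, 0) = a13[i];
    M(1, 2) = M(2, 1) = a23[i];
    arma::eig_sym(ev, evec, M);
    // sort by |lambda|
    arma::uvec ord = arma::sort_index(arma::abs(ev));
    l1[i] = ev(ord(0)); l2[i] = ev(ord(1)); l3[i] = ev(ord(2));
    v1[i] = evec(0, ord(0)); v2[i] = evec(1, ord(0)); v3[i] = evec(2, ord(0));
  }
  return List::create(_["l1"] = l1, _["l2"] = l2, _["l3"] = l3, _["v1"] = v1,
                      _["v2"] = v2, _["v3"] = v3);
}

// Fused convolution forward/backward: the im2col buffer lives only inside
// the C++ call (thread-local scratch, grow-only), so no multi-MB buffers
// are allocated per call or held across the training loop.
static std::vector<double>& convScratch(int which) {
  static std::vector<double> bufs[2];
  return bufs[which];
}

static void im2col2_into(const arma::cube& x, int k, int stride,
                         double* out, size_t rows) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int p = (k - 1) / 2;
  const int Ho = outDim(H, k, stride), Wo = outDim(W, k, stride);
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const size_t col = ki + static_cast<size_t>(k) * (kj + k * c);
        double* po = out + col * rows;
        for (int j = 0; j < Wo; ++j) {
          const int sj = j * stride - p + kj;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int si = i * stride - p + ki;
            if (si < 0 || si >= H) continue;
            po[i + static_cast<size_t>(Ho) * j] = x(si, sj, c);
          }
        }
      }
}

static void im2col3_into(const double* px, const IntegerVector& dims, int k,
                         int stride, double* out, size_t rows) {
  const int D1 = dims[0], D2 = dims[1], D3 = dims[2], C = dims[3];
  const int p = (k - 1) / 2;
  const int O1 = outDim(D1, k, stride), O2 = outDim(D2, k, stride),
            O3 = outDim(D3, k, stride);
  for (int c = 0; c < C; ++c)
    for (int k3 = 0; k3 < k; ++k3)
      for (int k2 = 0; k2 < k; ++k2)
        for (int k1 = 0; k1 < k; ++k1) {
          const size_t col =
              k1 + static_cast<size_t>(k) * (k2 + k * (k3 + k * c));
          double* po = out + col * rows;
          for (int i3 = 0; i3 < O3; ++i3) {
            const int s3 = i3 * stride - p + k3;
            if (s3 < 0 || s3 >= D3) continue;
            for (int i2 = 0; i2 < O2; ++i2) {
              const int s2 = i2 * stride - p + k2;
              if (s2 < 0 || s2 >= D2) continue;
              for (int i1 = 0; i1 < O1; ++i1) {
                const int s1 = i1 * stride - p + k1;
                if (s1 < 0 || s1 >= D1) continue;
                po[i1 + static_cast<size_t>(O1) * (i2 + O2 * i3)] =
                    px[s1 + static_cast<size_t>(D1) *
                                (s2 + static_cast<size_t>(D2) *
                                          (s3 + static_cast<size_t>(D3) * c))];
              }
            }
          }
        }
}

static double* scratchZeroed(int which, size_t n) {
  std::vector<double>& b = convScratch(which);
  if (b.size() < n) b.resize(n);
  std::fill(b.begin(), b.begin() + n, 0.0);
  return b.data();
}

// [[Rcpp::export(name = ".conv2Fwd")]]
arma::cube conv2Fwd(const arma::cube& x, const NumericVector& w,
                    const arma::vec& b, int stride) {
  const IntegerVector wd = w.attr("dim");
  const int k = wd[0], cin = wd[2], cout = wd[3];
  const int Ho = outDim(x.n_rows, k, stride), Wo = outDim(x.n_cols, k, stride);
  const size_t rows = static_cast<size_t>(Ho) * Wo;
  const size_t nc = static_cast<size_t>(k) * k * cin;
  double* buf = scratchZeroed(0, rows * nc);
  im2col2_into(x, k, stride, buf, rows);
  const arma::mat cols(buf, rows, nc, false, true);
  const arma::mat Wm(const_cast<double*>(w.begin()), nc, cout, false, true);
  arma::mat y = cols * Wm;
  y.each_row() += b.t();
  arma::cube out(Ho, Wo, cout);
  std::memcpy(out.memptr(), y.memptr(), sizeof(double) * y.n_elem);
  return out;
}

// [[Rcpp::export(name = ".conv2Bwd")]]
List conv2Bwd(const arma::cube& x, const NumericVector& w,
              const arma::cube& dy, int stride) {
  const IntegerVector wd = w.attr("dim");
  const int k = wd[0], cin = wd[2], cout = wd[3];
  const size_t rows = static_cast<size_t>(dy.n_rows) * dy.n_cols;
  const size_t nc = static_cast<size_t>(k) * k * cin;
  double* buf = scratchZeroed(0, rows * nc);
  im2col2_into(x, k, stride, buf, rows);
  const arma::mat cols(buf, rows, nc, false, true);
  arma::mat dym(const_cast<double*>(dy.memptr()), rows, cout, false, true);
  arma::mat gW = cols.t() * dym;
  arma::vec gb = arma::sum(dym, 0).t();
  const arma::mat Wm(const_cast<double*>(w.begin()), nc, cout, false, true);
  std::vector<double>& b1 = convScratch(1);
  if (b1.size() < rows * nc) b1.resize(rows * nc);
  arma::mat dcols(b1.data(), rows, nc, false, true);
  dcols = dym * Wm.t();
  arma::cube dx = col2im2(dcols, x.n_rows, x.n_cols, x.n_slices, k, stride);
  NumericVector gWv(gW.begin(), gW.end());
  gWv.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["gW"] = gWv,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// [[Rcpp::export(name = ".conv3Fwd")]]
NumericVector conv3Fwd(const NumericVector& x, const IntegerVector& dims,
                       const NumericVector& w, const arma::vec& b,
                       int stride) {
  const IntegerVector wd = w.attr("dim");
  const int k = wd[0], cin = wd[3], cout = wd[4];
  const int O1 = outDim(dims[0], k, stride), O2 = outDim(dims[1], k, stride),
            O3 = outDim(dims[2], k, stride);
  const size_t rows = static_cast<size_t>(O1) * O2 * O3;
  const size_t nc = static_cast<size_t>(k) * k * k * cin;
  double* buf = scratchZeroed(0, rows * nc);
  im2col3_into(x.begin(), dims, k, stride, buf, rows);
  const arma::mat cols(buf, rows, nc, false, true);
  const arma::mat Wm(const_cast<double*>(w.begin()), nc, cout, false, true);
  arma::mat y = cols * Wm;
  y.each_row() += b.t();
  NumericVector out(y.begin(), y.end());
  out.attr("dim") = IntegerVector::create(O1, O2, O3, cout);
  return out;
}

// [[Rcpp::export(name = ".conv3Bwd")]]
List conv3Bwd(const NumericVector& x, const IntegerVector& dims,
              const NumericVector& w, const NumericVector& dy, int stride) {
  const IntegerVector wd = w.attr("dim");
  const int k = wd[0], cin = wd[3], cout = wd[4];
  const int O1 = outDim(dims[0], k, stride), O2 = outDim(dims[1], k, stride),
            O3 = outDim(dims[2], k, stride);
  const size_t rows = static_cast<size_t>(O1) * O2 * O3;
  const size_t nc = static_cast<size_t>(k) * k * k * cin;
  double* buf = scratchZeroed(0, rows * nc);
  im2col3_into(x.begin(), dims, k, stride, buf, rows);
  const arma::mat cols(buf, rows, nc, false, true);
  arma::mat dym(const_cast<double*>(dy.begin()), rows, cout, false, true);
  arma::mat gW = cols.t() * dym;
  arma::vec gb = arma::sum(dym, 0).t();
  const arma::mat Wm(const_cast<double*>(w.begin()), nc, cout, false, true);
  std::vector<double>& b1 = convScratch(1);
  if (b1.size() < rows * nc) b1.resize(rows * nc);
  arma::mat dcols(b1.data(), rows, nc, false, true);
  dcols = dym * Wm.t();
  NumericVector dx = col2im3(dcols, dims, k, stride);
  NumericVector gWv(gW.begin(), gW.end());
  gWv.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["gW"] = gWv,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// Cap the BLAS thread pool (determinism + avoids oversubscription on small
// GEMMs); resolved dynamically so a plain reference BLAS is fine too.
#include <dlfcn.h>
// [[Rcpp::export(name = ".setBlasThreads")]]
bool setBlasThreads(int n) {
  typedef void (*setfn)(int);
  setfn f = (setfn)dlsym(RTLD_DEFAULT, "openblas_set_num_threads");
  if (f) {
    f(n);
    return true;
  }
  return false;
}
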