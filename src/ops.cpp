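#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Feature maps are stored channel-first as (C, Z, Y, X) numeric arrays;
// R is column-major, so matrix(x, nrow = C) gives one column per voxel.

static inline int out_len(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// Unfold a (C, Z, Y, X) array into a (C*kz*ky*kx, Lz*Ly*Lx) matrix of
// receptive fields (zero padding). Row index = c + C*(dz + kz*(dy + ky*dx)).
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, IntegerVector dims,
                         IntegerVector kernel, IntegerVector stride,
                         IntegerVector pad) {
  const int C = dims[0], Z = dims[1], Y = dims[2], X = dims[3];
  const int kz = kernel[0], ky = kernel[1], kx = kernel[2];
  const int sz = stride[0], sy = stride[1], sx = stride[2];
  const int pz = pad[0], py = pad[1], px = pad[2];
  const int Lz = out_len(Z, kz, sz, pz);
  const int Ly = out_len(Y, ky, sy, py);
  const int Lx = out_len(X, kx, sx, px);
  const int nrow = C * kz * ky * kx;
  const R_xlen_t L = (R_xlen_t)Lz * Ly * Lx;
  NumericMatrix out(nrow, L);
  const double *xp = x.begin();
  double *op = out.begin();
  for (int ox = 0; ox < Lx; ++ox) {
    for (int oy = 0; oy < Ly; ++oy) {
      for (int oz = 0; oz < Lz; ++oz) {
        R_xlen_t col = (R_xlen_t)oz + (R_xlen_t)Lz * (oy + (R_xlen_t)Ly * ox);
        double *dst = op + col * nrow;
        for (int dx = 0; dx < kx; ++dx) {
          int ix = ox * sx - px + dx;
          for (int dy = 0; dy < ky; ++dy) {
            int iy = oy * sy - py + dy;
            for (int dz = 0; dz < kz; ++dz) {
              int iz = oz * sz - pz + dz;
              R_xlen_t r = (R_xlen_t)C * (dz + kz * (dy + (R_xlen_t)ky * dx));
              if (iz < 0 || iz >= Z || iy < 0 || iy >= Y || ix < 0 || ix >= X) {
                for (int c = 0; c < C; ++c) dst[r + c] = 0.0;
              } else {
                const double *src =
                  xp + (R_xlen_t)C * (iz + (R_xlen_t)Z * (iy + (R_xlen_t)Y * ix));
                for (int c = 0; c < C; ++c) dst[r + c] = src[c];
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col_cpp: fold a column matrix back onto a (C, Z, Y, X) grid,
// accumulating overlaps. Used for conv input-gradients and transposed-conv
// forward passes (where kernel == stride makes the fold overlap-free).
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, IntegerVector dims,
                         IntegerVector kernel, IntegerVector stride,
                         IntegerVector pad) {
  const int C = dims[0], Z = dims[1], Y = dims[2], X = dims[3];
  const int kz = kernel[0], ky = kernel[1], kx = kernel[2];
  const int sz = stride[0], sy = stride[1], sx = stride[2];
  const int pz = pad[0], py = pad[1], px = pad[2];
  const int Lz = out_len(Z, kz, sz, pz);
  const int Ly = out_len(Y, ky, sy, py);
  const int Lx = out_len(X, kx, sx, px);
  const int nrow = C * kz * ky * kx;
  NumericVector out((R_xlen_t)C * Z * Y * X);
  out.attr("dim") = dims;
  double *op = out.begin();
  const double *cp = cols.begin();
  for (int ox = 0; ox < Lx; ++ox) {
    for (int oy = 0; oy < Ly; ++oy) {
      for (int oz = 0; oz < Lz; ++oz) {
        R_xlen_t col = (R_xlen_t)oz + (R_xlen_t)Lz * (oy + (R_xlen_t)Ly * ox);
        const double *src = cp + col * nrow;
        for (int dx = 0; dx < kx; ++dx) {
          int ix = ox * sx - px + dx;
          if (ix < 0 || ix >= X) continue;
          for (int dy = 0; dy < ky; ++dy) {
            int iy = oy * sy - py + dy;
            if (iy < 0 || iy >= Y) continue;
            for (int dz = 0; dz < kz; ++dz) {
              int iz = oz * sz - pz + dz;
              if (iz < 0 || iz >= Z) continue;
              R_xlen_t r = (R_xlen_t)C * (dz + kz * (dy + (R_xlen_t)ky * dx));
              double *dst =
                op + (R_xlen_t)C * (iz + (R_xlen_t)Z * (iy + (R_xlen_t)Y * ix));
              for (int c = 0; c < C; ++c) dst[c] += src[r + c];
            }
          }
        }
      }
    }
  }
  return out;
}

// Connected-component labelling of a binary (Z, Y, X) grid.
// connectivity: 6 (faces) or 26 (faces+edges+corners). Labels are assigned
// in first-encounter scan order (z fastest), so label ids are deterministic.
// [[Rcpp::export]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dims,
                           int connectivity) {
  const int Z = dims[0], Y = dims[1], X = dims[2];
  const R_xlen_t n = (R_xlen_t)Z * Y * X;
  IntegerVector lab(n, 0);
  lab.attr("dim") = dims;
  std::vector<std::array<int, 3>> offs;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        offs.push_back({dz, dy, dx});
      }
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    q.push(i);
    while (!q.empty()) {
      R_xlen_t cur = q.front(); q.pop();
      int cz = cur % Z;
      int cy = (cur / Z) % Y;
      int cx = cur / ((R_xlen_t)Z * Y);
      for (auto &o : offs) {
        int iz = cz + o[0], iy = cy + o[1], ix = cx + o[2];
        if (iz < 0 || iz >= Z || iy < 0 || iy >= Y || ix < 0 || ix >= X)
          continue;
        R_xlen_t j = iz + (R_xlen_t)Z * (iy + (R_xlen_t)Y * ix);
        if (mask[j] && lab[j] == 0) { lab[j] = next; q.push(j); }
      }
    }
  }
  return lab;
}

// For each row of a (n x 3) point matrix, the minimum Euclidean distance to
// any row of b (m x 3). Coordinates are physical (mm).
// [[Rcpp::export]]
NumericVector nn_min_dists_cpp(NumericMatrix a, NumericMatrix b) {
  const int n = a.nrow(), m = b.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    const double a0 = a(i, 0), a1 = a(i, 1), a2 = a(i, 2);
    for (int j = 0; j < m; ++j) {
      double d0 = a0 - b(j, 0), d1 = a1 - b(j, 1), d2 = a2 - b(j, 2);
      double d = d0 * d0 + d1 * d1 + d2 * d2;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Fused instance-norm + leaky-ReLU forward. x is (C, Z, Y, X); statistics
// are computed per channel, or per (channel, slice) when zgroups = Z
// (2D networks; slices are independent). Returns the activation, the
// normalized pre-activation and the inverse std needed for backward.
// [[Rcpp::export]]
List inorm_lrelu_fwd_cpp(NumericVector x, IntegerVector dims,
                         NumericVector gamma, NumericVector beta,
                         int zgroups, double slope, double eps) {
  const int C = dims[0];
  const R_xlen_t n = x.size();
  const int rows = C * zgroups;
  const R_xlen_t L = n / rows;
  NumericVector y(n), xhat(n);
  NumericVector istd(rows);
  y.attr("dim") = dims;
  const double *xp = x.begin();
  double *yp = y.begin(), *hp = xhat.begin();
  for (int r = 0; r < rows; ++r) {
    // strided row r of the (rows x L) view of x
    double s = 0, s2 = 0;
    for (R_xlen_t j = 0; j < L; ++j) {
      double v = xp[r + (R_xlen_t)rows * j];
      s += v; s2 += v * v;
    }
    double mu = s / L;
    double var = s2 / L - mu * mu;
    if (var < 0) var = 0;
    double is = 1.0 / std::sqrt(var + eps);
    istd[r] = is;
    double g = gamma[r % C], b = beta[r % C];
    for (R_xlen_t j = 0; j < L; ++j) {
      R_xlen_t k = r + (R_xlen_t)rows * j;
      double h = (xp[k] - mu) * is;
      hp[k] = h;
      double a = g * h + b;
      yp[k] = a > 0 ? a : slope * a;
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["istd"] = istd);
}

// Matching backward: dy is the gradient at the leaky-ReLU output.
// [[Rcpp::export]]
List inorm_lrelu_bwd_cpp(NumericVector dy, NumericVector xhat,
                         NumericVector istd, IntegerVector dims,
                         NumericVector gamma, NumericVector beta,
                         int zgroups, double slope) {
  const int C = dims[0];
  const R_xlen_t n = dy.size();
  const int rows = C * zgroups;
  const R_xlen_t L = n / rows;
  NumericVector dx(n);
  NumericVector dgamma(C), dbeta(C);
  dx.attr("dim") = dims;
  const double *dyp = dy.begin(), *hp = xhat.begin();
  double *dxp = dx.begin();
  for (int r = 0; r < rows; ++r) {
    double g = gamma[r % C], b = beta[r % C];
    double sum_dh = 0, sum_dhh = 0, dg = 0, db = 0;
    for (R_xlen_t j = 0; j < L; ++j) {
      R_xlen_t k = r + (R_xlen_t)rows * j;
      double h = hp[k];
      double act = g * h + b;
      double d = dyp[k] * (act > 0 ? 1.0 : slope);  // through leaky ReLU
      dg += d * h;
      db += d;
      double dh = d * g;
      sum_dh += dh;
      sum_dhh += dh * h;
    }
    dgamma[r % C] += dg;
    dbeta[r % C] += db;
    double m_dh = sum_dh / L, m_dhh = sum_dhh / L;
    double is = istd[r];
    for (R_xlen_t j = 0; j < L; ++j) {
      R_xlen_t k = r + (R_xlen_t)rows * j;
      double h = hp[k];
      double act = g * h + b;
      double d = dyp[k] * (act > 0 ? 1.0 : slope);
      double dh = d * g;
      dx[k] = (dh - m_dh - h * m_dhh) * is;
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
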