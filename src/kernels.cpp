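// Low-level numeric kernels for the segmentation network and surface-distance
// computations. Feature maps are stored as C x Nvox matrices with voxel linear
// index v = x + X*(y + Y*z) (0-based, x fastest). im2col rows are ordered
// r = c + C*(kx + 3*(ky + 3*kz)) with kernel offsets kx,ky,kz in {0,1,2}
// relative to -1 (3^3 kernels, zero padding 1 on every side).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_dim(int n, int stride) { return (n - 1) / stride + 1; }

// Fill the im2col buffer for output z-slab [z0, z1).
static void im2col_slab(const arma::mat& x, int X, int Y, int Z, int C,
                        int stride, int Xo, int Yo, int z0, int z1,
                        arma::mat& col) {
  const int K = 27 * C;
  col.zeros(K, (size_t)Xo * Yo * (z1 - z0));
  for (int oz = z0; oz < z1; ++oz) {
    for (int oy = 0; oy < Yo; ++oy) {
      for (int ox = 0; ox < Xo; ++ox) {
        const size_t vcol = (size_t)(ox) + (size_t)Xo * (oy + (size_t)Yo * (oz - z0));
        double* dst = col.colptr(vcol);
        for (int kz = 0; kz < 3; ++kz) {
          const int iz = oz * stride - 1 + kz;
          if (iz < 0 || iz >= Z) continue;
          for (int ky = 0; ky < 3; ++ky) {
            const int iy = oy * stride - 1 + ky;
            if (iy < 0 || iy >= Y) continue;
            for (int kx = 0; kx < 3; ++kx) {
              const int ix = ox * stride - 1 + kx;
              if (ix < 0 || ix >= X) continue;
              const size_t vin = (size_t)ix + (size_t)X * (iy + (size_t)Y * iz);
              const double* src = x.colptr(vin);
              double* d = dst + (size_t)C * (kx + 3 * (ky + 3 * kz));
              for (int c = 0; c < C; ++c) d[c] = src[c];
            }
          }
        }
      }
    }
  }
}

static int slab_size(int K, int Xo, int Yo, int Zo) {
  // keep the im2col buffer under ~64 MB
  double cap = 8.0e6;
  int bz = (int)std::floor(cap / ((double)K * Xo * Yo));
  if (bz < 1) bz = 1;
  if (bz > Zo) bz = Zo;
  return bz;
}

// [[Rcpp::export]]
arma::mat cpp_conv3d_fwd(const arma::mat& x, IntegerVector dims, int stride,
                         const arma::mat& W, const arma::vec& b) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const int C = x.n_rows;
  const int Xo = out_dim(X, stride), Yo = out_dim(Y, stride), Zo = out_dim(Z, stride);
  const int K = 27 * C;
  if ((int)W.n_cols != K) stop("weight/input channel mismatch");
  arma::mat y(W.n_rows, (size_t)Xo * Yo * Zo);
  const int bz = slab_size(K, Xo, Yo, Zo);
  arma::mat col;
  for (int z0 = 0; z0 < Zo; z0 += bz) {
    const int z1 = std::min(Zo, z0 + bz);
    im2col_slab(x, X, Y, Z, C, stride, Xo, Yo, z0, z1, col);
    y.cols((size_t)Xo * Yo * z0, (size_t)Xo * Yo * z1 - 1) = W * col;
  }
  y.each_col() += b;
  return y;
}

// Gradient w.r.t. the input: scatter-add of W^T dy through the im2col pattern.
// [[Rcpp::export]]
arma::mat cpp_conv3d_bwd_x(const arma::mat& dy, IntegerVector dims, int stride,
                           const arma::mat& W, int C_in) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const int Xo = out_dim(X, stride), Yo = out_dim(Y, stride), Zo = out_dim(Z, stride);
  arma::mat dx(C_in, (size_t)X * Y * Z, arma::fill::zeros);
  const int K = 27 * C_in;
  const int bz = slab_size(K, Xo, Yo, Zo);
  for (int z0 = 0; z0 < Zo; z0 += bz) {
    const int z1 = std::min(Zo, z0 + bz);
    arma::mat dcol = W.t() * dy.cols((size_t)Xo * Yo * z0, (size_t)Xo * Yo * z1 - 1);
    for (int oz = z0; oz < z1; ++oz) {
      for (int oy = 0; oy < Yo; ++oy) {
        for (int ox = 0; ox < Xo; ++ox) {
          const size_t vcol = (size_t)(ox) + (size_t)Xo * (oy + (size_t)Yo * (oz - z0));
          const double* src = dcol.colptr(vcol);
          for (int kz = 0; kz < 3; ++kz) {
            const int iz = oz * stride - 1 + kz;
            if (iz < 0 || iz >= Z) continue;
            for (int ky = 0; ky < 3; ++ky) {
              const int iy = oy * stride - 1 + ky;
              if (iy < 0 || iy >= Y) continue;
              for (int kx = 0; kx < 3; ++kx) {
                const int ix = ox * stride - 1 + kx;
                if (ix < 0 || ix >= X) continue;
                const size_t vin = (size_t)ix + (size_t)X * (iy + (size_t)Y * iz);
                double* d = dx.colptr(vin);
                const double* s = src + (size_t)C_in * (kx + 3 * (ky + 3 * kz));
                for (int c = 0; c < C_in; ++c) d[c] += s[c];
              }
            }
          }
        }
      }
    }
  }
  return dx;
}

// Gradients w.r.t. weights and bias.
// [[Rcpp::export]]
List cpp_conv3d_bwd_w(const arma::mat& x, IntegerVector dims, int stride,
                      const arma::mat& dy) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const int C = x.n_rows;
  const int Xo = out_dim(X, stride), Yo = out_dim(Y, stride), Zo = out_dim(Z, stride);
  const int K = 27 * C;
  arma::mat dW(dy.n_rows, K, arma::fill::zeros);
  const int bz = slab_size(K, Xo, Yo, Zo);
  arma::mat col;
  for (int z0 = 0; z0 < Zo; z0 += bz) {
    const int z1 = std::min(Zo, z0 + bz);
    im2col_slab(x, X, Y, Z, C, stride, Xo, Yo, z0, z1, col);
    dW += dy.cols((size_t)Xo * Yo * z0, (size_t)Xo * Yo * z1 - 1) * col.t();
  }
  arma::vec db = arma::sum(dy, 1);
  return List::create(Named("dW") = dW, Named("db") = db);
}

struct LinTab { std::vector<int> i0, i1; std::vector<double> w0; };

// half-voxel-aligned factor-2 interpolation table (clamped at the edges)
static LinTab up2_table(int n) {
  LinTab t;
  const int m = 2 * n;
  t.i0.resize(m); t.i1.resize(m); t.w0.resize(m);
  for (int o = 0; o < m; ++o) {
    double s = (o + 0.5) / 2.0 - 0.5;
    if (s < 0) s = 0;
    if (s > n - 1) s = n - 1;
    int i0 = (int)std::floor(s);
    if (i0 > n - 2) i0 = std::max(0, n - 2);
    double f = s - i0;
    t.i0[o] = i0; t.i1[o] = std::min(n - 1, i0 + 1); t.w0[o] = 1.0 - f;
  }
  return t;
}

// [[Rcpp::export]]
arma::mat cpp_upsample2(const arma::mat& x, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const int C = x.n_rows;
  LinTab tx = up2_table(X), ty = up2_table(Y), tz = up2_table(Z);
  const int Xo = 2 * X, Yo = 2 * Y, Zo = 2 * Z;
  arma::mat y(C, (size_t)Xo * Yo * Zo);
  arma::vec acc(C);
  for (int oz = 0; oz < Zo; ++oz) {
    for (int oy = 0; oy < Yo; ++oy) {
      for (int ox = 0; ox < Xo; ++ox) {
        acc.zeros();
        for (int cz = 0; cz < 2; ++cz) {
          const int iz = cz ? tz.i1[oz] : tz.i0[oz];
          const double wz = cz ? 1.0 - tz.w0[oz] : tz.w0[oz];
          if (wz == 0) continue;
          for (int cy = 0; cy < 2; ++cy) {
            const int iy = cy ? ty.i1[oy] : ty.i0[oy];
            const double wy = cy ? 1.0 - ty.w0[oy] : ty.w0[oy];
            if (wy == 0) continue;
            for (int cx = 0; cx < 2; ++cx) {
              const int ix = cx ? tx.i1[ox] : tx.i0[ox];
              const double wx = cx ? 1.0 - tx.w0[ox] : tx.w0[ox];
              if (wx == 0) continue;
              const size_t vin = (size_t)ix + (size_t)X * (iy + (size_t)Y * iz);
              acc += (wx * wy * wz) * x.col(vin);
            }
          }
        }
        y.col((size_t)ox + (size_t)Xo * (oy + (size_t)Yo * oz)) = acc;
      }
    }
  }
  return y;
}

// adjoint of cpp_upsample2 (scatter-add with the same weights)
// [[Rcpp::export]]
arma::mat cpp_upsample2_adj(const arma::mat& dy, IntegerVector indims) {
  const int X = indims[0], Y = indims[1], Z = indims[2];
  const int C = dy.n_rows;
  LinTab tx = up2_table(X), ty = up2_table(Y), tz = up2_table(Z);
  const int Xo = 2 * X, Yo = 2 * Y, Zo = 2 * Z;
  arma::mat dx(C, (size_t)X * Y * Z, arma::fill::zeros);
  for (int oz = 0; oz < Zo; ++oz) {
    for (int oy = 0; oy < Yo; ++oy) {
      for (int ox = 0; ox < Xo; ++ox) {
        const arma::vec g = dy.col((size_t)ox + (size_t)Xo * (oy + (size_t)Yo * oz));
        for (int cz = 0; cz < 2; ++cz) {
          const int iz = cz ? tz.i1[oz] : tz.i0[oz];
          const double wz = cz ? 1.0 - tz.w0[oz] : tz.w0[oz];
          if (wz == 0) continue;
          for (int cy = 0; cy < 2; ++cy) {
            const int iy = cy ? ty.i1[oy] : ty.i0[oy];
            const double wy = cy ? 1.0 - ty.w0[oy] : ty.w0[oy];
            if (wy == 0) continue;
            for (int cx = 0; cx < 2; ++cx) {
              const int ix = cx ? tx.i1[ox] : tx.i0[ox];
              const double wx = cx ? 1.0 - tx.w0[ox] : tx.w0[ox];
              if (wx == 0) continue;
              dx.col((size_t)ix + (size_t)X * (iy + (size_t)Y * iz)) += (wx * wy * wz) * g;
            }
          }
        }
      }
    }
  }
  return dx;
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher) on samples at
// physical positions i*h; f holds squared distances, overwritten with result.
static void dt1d(const std::vector<double>& f, double h, std::vector<int>& v,
                 std::vector<double>& zbound, std::vector<double>& out) {
  const int n = (int)f.size();
  int k = -1; // lower envelope over finite samples only
  for (int q = 0; q < n; ++q) {
    if (f[q] == HUGE_VAL) continue;
    double s = -HUGE_VAL;
    while (k >= 0) {
      s = ((f[q] + (double)q * q * h * h) - (f[v[k]] + (double)v[k] * v[k] * h * h)) /
          (2.0 * h * (q - v[k]));
      if (s <= zbound[k]) { --k; continue; }
      break;
    }
    ++k;
    v[k] = q;
    zbound[k] = (k == 0) ? -HUGE_VAL : s;
    zbound[k + 1] = HUGE_VAL;
  }
  if (k < 0) { // no finite sample in this line
    for (int q = 0; q < n; ++q) out[q] = HUGE_VAL;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    const double x = q * h;
    while (zbound[k + 1] < x) ++k;
    const double d = x - v[k] * h;
    out[q] = d * d + f[v[k]];
  }
}

// Exact Euclidean distance (mm) from every voxel center to the nearest site
// voxel center, with anisotropic spacing.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector sites, IntegerVector dims, NumericVector spacing) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const size_t N = (size_t)X * Y * Z;
  std::vector<double> d(N);
  for (size_t i = 0; i < N; ++i) d[i] = sites[i] ? 0.0 : HUGE_VAL;
  const int nmax = std::max(X, std::max(Y, Z));
  std::vector<double> f(nmax), out(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);
  // along x
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y) {
      const size_t base = (size_t)X * (y + (size_t)Y * z);
      f.assign(d.begin() + base, d.begin() + base + X);
      f.resize(X);
      dt1d(f, spacing[0], v, zb, out);
      for (int x = 0; x < X; ++x) d[base + x] = out[x];
    }
  // along y
  for (int z = 0; z < Z; ++z)
    for (int x = 0; x < X; ++x) {
      f.resize(Y);
      for (int y = 0; y < Y; ++y) f[y] = d[(size_t)x + (size_t)X * (y + (size_t)Y * z)];
      dt1d(f, spacing[1], v, zb, out);
      for (int y = 0; y < Y; ++y) d[(size_t)x + (size_t)X * (y + (size_t)Y * z)] = out[y];
    }
  // along z
  for (int y = 0; y < Y; ++y)
    for (int x = 0; x < X; ++x) {
      f.resize(Z);
      for (int z = 0; z < Z; ++z) f[z] = d[(size_t)x + (size_t)X * (y + (size_t)Y * z)];
      dt1d(f, spacing[2], v, zb, out);
      for (int z = 0; z < Z; ++z) d[(size_t)x + (size_t)X * (y + (size_t)Y * z)] = out[z];
    }
  NumericVector res(N);
  for (size_t i = 0; i < N; ++i) res[i] = (d[i] == HUGE_VAL) ? NA_REAL : std::sqrt(d[i]);
  return res;
}

// For each row of src, the minimum Euclidean distance to any row of dst.
// [[Rcpp::export]]
NumericVector cpp_min_dists(const arma::mat& src, const arma::mat& dst) {
  const size_t n = src.n_rows, m = dst.n_rows;
  NumericVector out(n);
  for (size_t i = 0; i < n; ++i) {
    double best = HUGE_VAL;
    const double sx = src(i, 0), sy = src(i, 1), sz = src(i, 2);
    for (size_t j = 0; j < m; ++j) {
      const double dx = sx - dst(j, 0), dy = sy - dst(j, 1), dz = sz - dst(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
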