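// Voxel-volume primitives: anisotropic Euclidean distance transform
// (Felzenszwalb-Huttenlocher lower envelope) and the 3D conv-net operators
// (im2col+GEMM convolution, max-pooling, trilinear upsampling) used by the
// dose-prediction network. Volumes are stored in R array order (x fastest);
// feature maps as (Nvox x C) matrices.
#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double INF = 1e20;

// 1D squared distance transform on a grid with step `s` (mm).
static void dt1d(const double* f, double* d, int n, double s) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  const double s2 = s * s;
  for (int q = 1; q < n; ++q) {
    double fq = f[q] + s2 * q * q;
    double sep = (fq - (f[v[k]] + s2 * v[k] * v[k])) / (2.0 * s2 * (q - v[k]));
    while (sep <= z[k]) {
      --k;
      sep = (fq - (f[v[k]] + s2 * v[k] * v[k])) / (2.0 * s2 * (q - v[k]));
    }
    ++k; v[k] = q; z[k] = sep; z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = s * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// Euclidean distance (mm) from every voxel to the nearest TRUE voxel.
// [[Rcpp::export(name = ".edt_mm")]]
NumericVector edt_mm(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = mask[i] ? 0.0 : INF;
  std::vector<double> buf(std::max(nx, std::max(ny, nz)));
  std::vector<double> out(std::max(nx, std::max(ny, nz)));
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy) {
      double* row = &d[(R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)];
      dt1d(row, out.data(), nx, spacing[0]);
      std::copy(out.begin(), out.begin() + nx, row);
    }
  for (int iz = 0; iz < nz; ++iz)
    for (int ix = 0; ix < nx; ++ix) {
      for (int iy = 0; iy < ny; ++iy) buf[iy] = d[ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)];
      dt1d(buf.data(), out.data(), ny, spacing[1]);
      for (int iy = 0; iy < ny; ++iy) d[ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)] = out[iy];
    }
  for (int iy = 0; iy < ny; ++iy)
    for (int ix = 0; ix < nx; ++ix) {
      for (int iz = 0; iz < nz; ++iz) buf[iz] = d[ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)];
      dt1d(buf.data(), out.data(), nz, spacing[2]);
      for (int iz = 0; iz < nz; ++iz) d[ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)] = out[iz];
    }
  NumericVector res(n);
  for (R_xlen_t i = 0; i < n; ++i) res[i] = std::sqrt(d[i]);
  return res;
}

// ---- convolution -----------------------------------------------------------
//
// Same-padded k x k x k convolution via im2col + GEMM, processed in z-slabs
// to bound the im2col buffer. The col block is (nvox_slab x k^3*Cin) with
// feature column index c*k^3 + offset; W is (Cout x k^3*Cin).

// Fill col for output slices [z0, z1).
static void im2col_slab(const arma::mat& X, int nx, int ny, int nz,
                        int k, int z0, int z1, arma::mat& col) {
  const int r = k / 2, k3 = k * k * k;
  const int Cin = X.n_cols;
  const R_xlen_t plane = (R_xlen_t)nx * ny;
  for (int c = 0; c < Cin; ++c) {
    const double* xc = X.colptr(c);
    for (int koff = 0; koff < k3; ++koff) {
      const int dx = koff % k - r, dy = (koff / k) % k - r, dz = koff / (k * k) - r;
      double* colp = col.colptr(c * k3 + koff);
      for (int iz = z0; iz < z1; ++iz) {
        double* slab = colp + (R_xlen_t)(iz - z0) * plane;
        const int jz = iz + dz;
        if (jz < 0 || jz >= nz) { std::memset(slab, 0, plane * sizeof(double)); continue; }
        const double* xplane = xc + (R_xlen_t)jz * plane;
        for (int iy = 0; iy < ny; ++iy) {
          double* dst = slab + (R_xlen_t)iy * nx;
          const int jy = iy + dy;
          if (jy < 0 || jy >= ny) { std::memset(dst, 0, nx * sizeof(double)); continue; }
          const double* srow = xplane + (R_xlen_t)jy * nx + dx;
          const int lo = std::max(0, -dx), hi = std::min(nx, nx - dx);
          for (int ix = 0; ix < lo; ++ix) dst[ix] = 0.0;
          std::memcpy(dst + lo, srow + lo, (size_t)(hi - lo) * sizeof(double));
          for (int ix = hi; ix < nx; ++ix) dst[ix] = 0.0;
        }
      }
    }
  }
}

// Scatter-add dcol (nvox_slab x k^3*Cin) for slices [z0, z1) into dX.
static void col2im_slab(const arma::mat& dcol, int nx, int ny, int nz,
                        int k, int z0, int z1, arma::mat& dX) {
  const int r = k / 2, k3 = k * k * k;
  const int Cin = dX.n_cols;
  const R_xlen_t plane = (R_xlen_t)nx * ny;
  for (int c = 0; c < Cin; ++c) {
    double* gxc = dX.colptr(c);
    for (int koff = 0; koff < k3; ++koff) {
      const int dx = koff % k - r, dy = (koff / k) % k - r, dz = koff / (k * k) - r;
      const double* colp = dcol.colptr(c * k3 + koff);
      for (int iz = z0; iz < z1; ++iz) {
        const double* slab = colp + (R_xlen_t)(iz - z0) * plane;
        const int jz = iz + dz;
        if (jz < 0 || jz >= nz) continue;
        double* gplane = gxc + (R_xlen_t)jz * plane;
        for (int iy = 0; iy < ny; ++iy) {
          const int jy = iy + dy;
          if (jy < 0 || jy >= ny) continue;
          const double* src = slab + (R_xlen_t)iy * nx;
          double* drow = gplane + (R_xlen_t)jy * nx + dx;
          const int lo = std::max(0, -dx), hi = std::min(nx, nx - dx);
          for (int ix = lo; ix < hi; ++ix) drow[ix] += src[ix];
        }
      }
    }
  }
}

static int slab_slices(int nx, int ny, int nz, int k, int Cin) {
  const double budget = 8.0e6;  // doubles in one col block (~64 MB)
  const double per_slice = (double)nx * ny * k * k * k * Cin;
  int slices = std::max(1, (int)(budget / per_slice));
  return std::min(slices, nz);
}

// [[Rcpp::export(name = ".conv3d_fwd")]]
arma::mat conv3d_fwd(const arma::mat& X, IntegerVector dims,
                     const arma::mat& W, const arma::vec& b, int k) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz, plane = (R_xlen_t)nx * ny;
  arma::mat Y(n, W.n_rows);
  const int step = slab_slices(nx, ny, nz, k, X.n_cols);
  static thread_local arma::mat col;  // persistent scratch: avoids page-fault churn
  if ((R_xlen_t)col.n_rows < (R_xlen_t)step * plane || col.n_cols != W.n_cols)
    col.set_size((R_xlen_t)step * plane, W.n_cols);
  for (int z0 = 0; z0 < nz; z0 += step) {
    const int z1 = std::min(nz, z0 + step);
    const R_xlen_t nvox = (R_xlen_t)(z1 - z0) * plane;
    arma::mat colv(col.memptr(), nvox, W.n_cols, false, true);
    im2col_slab(X, nx, ny, nz, k, z0, z1, colv);
    Y.rows((R_xlen_t)z0 * plane, (R_xlen_t)z1 * plane - 1) = colv * W.t();
  }
  Y.each_row() += b.t();
  return Y;
}

// [[Rcpp::export(name = ".conv3d_bwd")]]
List conv3d_bwd(const arma::mat& X, IntegerVector dims, const arma::mat& W,
                const arma::mat& dY, int k) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t plane = (R_xlen_t)nx * ny;
  const int k3 = k * k * k, Cin = X.n_cols, Cout = W.n_rows;
  arma::mat dW(W.n_rows, W.n_cols, arma::fill::zeros);
  arma::vec db = arma::sum(dY, 0).t();
  // weight gradient: accumulate dY' * im2col(X) slab by slab
  const int step = slab_slices(nx, ny, nz, k, Cin);
  static thread_local arma::mat col;
  if ((R_xlen_t)col.n_rows < (R_xlen_t)step * plane || col.n_cols != W.n_cols)
    col.set_size((R_xlen_t)step * plane, W.n_cols);
  for (int z0 = 0; z0 < nz; z0 += step) {
    const int z1 = std::min(nz, z0 + step);
    const R_xlen_t nvox = (R_xlen_t)(z1 - z0) * plane;
    arma::mat colv(col.memptr(), nvox, W.n_cols, false, true);
    im2col_slab(X, nx, ny, nz, k, z0, z1, colv);
    dW += dY.rows((R_xlen_t)z0 * plane, (R_xlen_t)z1 * plane - 1).t() * colv;
  }
  // data gradient: correlation of dY with the axis-flipped kernels, i.e. a
  // forward convolution with W rearranged to (Cin x k^3*Cout)
  arma::mat Wflip(Cin, (R_xlen_t)k3 * Cout);
  for (int c = 0; c < Cin; ++c)
    for (int co = 0; co < Cout; ++co)
      for (int koff = 0; koff < k3; ++koff)
        Wflip(c, (R_xlen_t)co * k3 + (k3 - 1 - koff)) = W(co, (R_xlen_t)c * k3 + koff);
  arma::mat dX = conv3d_fwd(dY, dims, Wflip, arma::vec(Cin, arma::fill::zeros), k);
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// ---- 2x max pooling --------------------------------------------------------

// [[Rcpp::export(name = ".maxpool3d_fwd")]]
List maxpool3d_fwd(const arma::mat& X, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  const int C = X.n_cols;
  const R_xlen_t no = (R_xlen_t)ox * oy * oz;
  arma::mat Y(no, C);
  arma::umat idx(no, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = X.colptr(c);
    for (int iz = 0; iz < oz; ++iz)
      for (int iy = 0; iy < oy; ++iy)
        for (int ix = 0; ix < ox; ++ix) {
          double best = -INF; R_xlen_t bi = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                const R_xlen_t src = (2 * ix + dx) +
                  (R_xlen_t)nx * ((2 * iy + dy) + (R_xlen_t)ny * (2 * iz + dz));
                if (xc[src] > best) { best = xc[src]; bi = src; }
              }
          const R_xlen_t o = ix + (R_xlen_t)ox * (iy + (R_xlen_t)oy * iz);
          Y(o, c) = best; idx(o, c) = bi;
        }
  }
  return List::create(_["Y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool3d_bwd")]]
arma::mat maxpool3d_bwd(const arma::mat& dY, const arma::umat& idx, double n_in) {
  const int C = dY.n_cols;
  arma::mat dX((R_xlen_t)n_in, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (arma::uword o = 0; o < dY.n_rows; ++o)
      dX(idx(o, c), c) += dY(o, c);
  return dX;
}

// ---- trilinear 2x upsampling ----------------------------------------------

static void up_axis(int n_out, int n_in, std::vector<int>& i0,
                    std::vector<int>& i1, std::vector<double>& w1) {
  i0.resize(n_out); i1.resize(n_out); w1.resize(n_out);
  for (int i = 0; i < n_out; ++i) {
    double u = (i + 0.5) / 2.0 - 0.5;
    int lo = (int)std::floor(u);
    double w = u - lo;
    if (lo < 0) { lo = 0; w = 0.0; }
    if (lo >= n_in - 1) { lo = n_in - 1; w = 0.0; }
    i0[i] = lo; i1[i] = std::min(lo + 1, n_in - 1); w1[i] = w;
  }
}

// [[Rcpp::export(name = ".upsample3d_fwd")]]
arma::mat upsample3d_fwd(const arma::mat& X, IntegerVector dims_in) {
  const int nx = dims_in[0], ny = dims_in[1], nz = dims_in[2];
  const int ox = 2 * nx, oy = 2 * ny, oz = 2 * nz;
  const int C = X.n_cols;
  std::vector<int> x0, x1, y0, y1, z0, z1;
  std::vector<double> wx, wy, wz;
  up_axis(ox, nx, x0, x1, wx); up_axis(oy, ny, y0, y1, wy); up_axis(oz, nz, z0, z1, wz);
  arma::mat Y((R_xlen_t)ox * oy * oz, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = X.colptr(c);
    double* yc = Y.colptr(c);
    R_xlen_t o = 0;
    for (int iz = 0; iz < oz; ++iz)
      for (int iy = 0; iy < oy; ++iy) {
        const double wzv = wz[iz], wyv = wy[iy];
        const R_xlen_t b00 = (R_xlen_t)nx * (y0[iy] + (R_xlen_t)ny * z0[iz]);
        const R_xlen_t b01 = (R_xlen_t)nx * (y0[iy] + (R_xlen_t)ny * z1[iz]);
        const R_xlen_t b10 = (R_xlen_t)nx * (y1[iy] + (R_xlen_t)ny * z0[iz]);
        const R_xlen_t b11 = (R_xlen_t)nx * (y1[iy] + (R_xlen_t)ny * z1[iz]);
        const double w00 = (1 - wyv) * (1 - wzv), w01 = (1 - wyv) * wzv;
        const double w10 = wyv * (1 - wzv), w11 = wyv * wzv;
        for (int ix = 0; ix < ox; ++ix, ++o) {
          const int ja = x0[ix], jb = x1[ix];
          const double wxv = wx[ix];
          const double va = w00 * xc[b00 + ja] + w01 * xc[b01 + ja] +
                            w10 * xc[b10 + ja] + w11 * xc[b11 + ja];
          const double vb = w00 * xc[b00 + jb] + w01 * xc[b01 + jb] +
                            w10 * xc[b10 + jb] + w11 * xc[b11 + jb];
          yc[o] = (1 - wxv) * va + wxv * vb;
        }
      }
  }
  return Y;
}

// Transpose of the trilinear upsampling (scatter-add of the same weights).
// [[Rcpp::export(name = ".upsample3d_bwd")]]
arma::mat upsample3d_bwd(const arma::mat& dY, IntegerVector dims_in) {
  const int nx = dims_in[0], ny = dims_in[1], nz = dims_in[2];
  const int ox = 2 * nx, oy = 2 * ny, oz = 2 * nz;
  const int C = dY.n_cols;
  std::vector<int> x0, x1, y0, y1, z0, z1;
  std::vector<double> wx, wy, wz;
  up_axis(ox, nx, x0, x1, wx); up_axis(oy, ny, y0, y1, wy); up_axis(oz, nz, z0, z1, wz);
  arma::mat dX((R_xlen_t)nx * ny * nz, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* gyc = dY.colptr(c);
    double* gxc = dX.colptr(c);
    R_xlen_t o = 0;
    for (int iz = 0; iz < oz; ++iz)
      for (int iy = 0; iy < oy; ++iy) {
        const double wzv = wz[iz], wyv = wy[iy];
        const R_xlen_t b00 = (R_xlen_t)nx * (y0[iy] + (R_xlen_t)ny * z0[iz]);
        const R_xlen_t b01 = (R_xlen_t)nx * (y0[iy] + (R_xlen_t)ny * z1[iz]);
        const R_xlen_t b10 = (R_xlen_t)nx * (y1[iy] + (R_xlen_t)ny * z0[iz]);
        const R_xlen_t b11 = (R_xlen_t)nx * (y1[iy] + (R_xlen_t)ny * z1[iz]);
        const double w00 = (1 - wyv) * (1 - wzv), w01 = (1 - wyv) * wzv;
        const double w10 = wyv * (1 - wzv), w11 = wyv * wzv;
        for (int ix = 0; ix < ox; ++ix, ++o) {
          const double g = gyc[o];
          if (g == 0.0) continue;
          const int ja = x0[ix], jb = x1[ix];
          const double ga = (1 - wx[ix]) * g, gb = wx[ix] * g;
          gxc[b00 + ja] += w00 * ga; gxc[b01 + ja] += w01 * ga;
          gxc[b10 + ja] += w10 * ga; gxc[b11 + ja] += w11 * ga;
          gxc[b00 + jb] += w00 * gb; gxc[b01 + jb] += w01 * gb;
          gxc[b10 + jb] += w10 * gb; gxc[b11 + jb] += w11 * gb;
        }
      }
  }
  return dX;
}
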