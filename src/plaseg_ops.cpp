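#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are stored in R as nvox x C matrices, voxel linear index
// ix + nx*(iy + ny*iz) (0-based here, 1-based in R), x fastest as in R arrays.

// Patch matrix layout: nvox rows, C*k^3 columns (column c*k3+j holds the
// j-th kernel offset of channel c), so every inner write/read runs down a
// contiguous column.
// [[Rcpp::export]]
NumericMatrix cpp_im2col3(const NumericMatrix& x, const IntegerVector& dims,
                          const int k, const int pad) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nvox = nx * ny * nz, C = x.ncol(), k3 = k * k * k;
  NumericMatrix cols(nvox, C * k3);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, c);
    int j = 0;
    for (int dz = 0; dz < k; ++dz)
      for (int dy = 0; dy < k; ++dy)
        for (int dx = 0; dx < k; ++dx, ++j) {
          const int ox = dx - pad, oy = dy - pad, oz = dz - pad;
          double* col = &cols(0, c * k3 + j);
          for (int iz = 0; iz < nz; ++iz) {
            const int sz = iz + oz;
            if (sz < 0 || sz >= nz) continue;
            for (int iy = 0; iy < ny; ++iy) {
              const int sy = iy + oy;
              if (sy < 0 || sy >= ny) continue;
              const double* src = xc + nx * (sy + ny * sz);
              double* dst = col + nx * (iy + ny * iz);
              const int x0 = (ox < 0) ? -ox : 0;
              const int x1 = (ox > 0) ? nx - ox : nx;
              for (int ix = x0; ix < x1; ++ix)
                dst[ix] = src[ix + ox];
            }
          }
        }
  }
  return cols;
}

// [[Rcpp::export]]
NumericMatrix cpp_col2im3(const NumericMatrix& cols, const IntegerVector& dims,
                          const int C, const int k, const int pad) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nvox = nx * ny * nz, k3 = k * k * k;
  NumericMatrix out(nvox, C);
  for (int c = 0; c < C; ++c) {
    double* oc = &out(0, c);
    int j = 0;
    for (int dz = 0; dz < k; ++dz)
      for (int dy = 0; dy < k; ++dy)
        for (int dx = 0; dx < k; ++dx, ++j) {
          const int ox = dx - pad, oy = dy - pad, oz = dz - pad;
          const double* col = &cols(0, c * k3 + j);
          for (int iz = 0; iz < nz; ++iz) {
            const int sz = iz + oz;
            if (sz < 0 || sz >= nz) continue;
            for (int iy = 0; iy < ny; ++iy) {
              const int sy = iy + oy;
              if (sy < 0 || sy >= ny) continue;
              double* dst = oc + nx * (sy + ny * sz);
              const double* src = col + nx * (iy + ny * iz);
              const int x0 = (ox < 0) ? -ox : 0;
              const int x1 = (ox > 0) ? nx - ox : nx;
              for (int ix = x0; ix < x1; ++ix)
                dst[ix + ox] += src[ix];
            }
          }
        }
  }
  return out;
}

// 2x2x2 max pooling; dims must be even. Returns pooled values and the 1-based
// linear row index of each argmax so the backward pass can scatter gradients.
// [[Rcpp::export]]
List cpp_maxpool3(const NumericMatrix& x, const IntegerVector& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int mx = nx / 2, my = ny / 2, mz = nz / 2;
  const int C = x.ncol();
  NumericMatrix y(mx * my * mz, C);
  IntegerMatrix idx(mx * my * mz, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, c);
    for (int iz = 0; iz < mz; ++iz)
      for (int iy = 0; iy < my; ++iy)
        for (int ix = 0; ix < mx; ++ix) {
          double best = R_NegInf; int besti = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                const int li = (2 * ix + dx) + nx * ((2 * iy + dy) + ny * (2 * iz + dz));
                if (xc[li] > best) { best = xc[li]; besti = li; }
              }
          const int oi = ix + mx * (iy + my * iz);
          y(oi, c) = best;
          idx(oi, c) = besti + 1;
        }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool3_bw(const NumericMatrix& dy, const IntegerMatrix& idx,
                              const int nvox) {
  const int C = dy.ncol(), n = dy.nrow();
  NumericMatrix dx(nvox, C);
  for (int c = 0; c < C; ++c)
    for (int i = 0; i < n; ++i)
      dx(idx(i, c) - 1, c) += dy(i, c);
  return dx;
}

// Directed minimum distances: for each point (row, mm) in a, the distance to
// the closest point in b. Brute force; surface point sets are small.
// [[Rcpp::export]]
NumericVector cpp_min_dists(const NumericMatrix& a, const NumericMatrix& b) {
  const int na = a.nrow(), nb = b.nrow();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    const double ax = a(i, 0), ay = a(i, 1), az = a(i, 2);
    for (int j = 0; j < nb; ++j) {
      const double dx = ax - b(j, 0), dy = ay - b(j, 1), dz = az - b(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
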