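// Low-level 3D volume kernels: interpolation, separable Gaussian filtering,
// exact Euclidean distance transform, connected-component labeling, gradients.
// All arrays are column-major (R layout), voxel indices 0-based.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
#include <limits>

using namespace Rcpp;

static inline R_xlen_t vidx(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// Sample a 3D volume at continuous 0-based voxel coordinates.
// order: 0 = nearest, 1 = trilinear. Points outside the grid return `fill`
// (for trilinear, points within half a voxel of the edge are clamped).
// [[Rcpp::export]]
NumericVector cpp_sample3d(const NumericVector& data, const IntegerVector& dim,
                           const NumericMatrix& pts, int order, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = pts.nrow();
  NumericVector out(n);
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (ISNAN(x) || ISNAN(y) || ISNAN(z)) { out[p] = fill; continue; }
    if (order == 0) {
      int i = (int)std::lround(x), j = (int)std::lround(y), k = (int)std::lround(z);
      if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) { out[p] = fill; continue; }
      out[p] = data[vidx(i, j, k, nx, ny)];
    } else {
      if (x < -0.5 || y < -0.5 || z < -0.5 ||
          x > nx - 0.5 || y > ny - 0.5 || z > nz - 0.5) { out[p] = fill; continue; }
      if (x < 0) x = 0; if (y < 0) y = 0; if (z < 0) z = 0;
      if (x > nx - 1) x = nx - 1; if (y > ny - 1) y = ny - 1; if (z > nz - 1) z = nz - 1;
      int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
      if (i0 > nx - 2) i0 = nx - 2; if (j0 > ny - 2) j0 = ny - 2; if (k0 > nz - 2) k0 = nz - 2;
      if (nx == 1) i0 = 0; if (ny == 1) j0 = 0; if (nz == 1) k0 = 0;
      double fx = x - i0, fy = y - j0, fz = z - k0;
      int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1), k1 = std::min(k0 + 1, nz - 1);
      double c000 = data[vidx(i0, j0, k0, nx, ny)], c100 = data[vidx(i1, j0, k0, nx, ny)];
      double c010 = data[vidx(i0, j1, k0, nx, ny)], c110 = data[vidx(i1, j1, k0, nx, ny)];
      double c001 = data[vidx(i0, j0, k1, nx, ny)], c101 = data[vidx(i1, j0, k1, nx, ny)];
      double c011 = data[vidx(i0, j1, k1, nx, ny)], c111 = data[vidx(i1, j1, k1, nx, ny)];
      double c00 = c000 * (1 - fx) + c100 * fx;
      double c10 = c010 * (1 - fx) + c110 * fx;
      double c01 = c001 * (1 - fx) + c101 * fx;
      double c11 = c011 * (1 - fx) + c111 * fx;
      double c0 = c00 * (1 - fy) + c10 * fy;
      double c1 = c01 * (1 - fy) + c11 * fy;
      out[p] = c0 * (1 - fz) + c1 * fz;
    }
  }
  return out;
}

static void gauss_kernel(double sigma, std::vector<double>& k) {
  int r = (int)std::ceil(4.0 * sigma);
  if (r < 1) r = 1;
  k.assign(2 * r + 1, 0.0);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    double v = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    k[i + r] = v; s += v;
  }
  for (size_t i = 0; i < k.size(); ++i) k[i] /= s;
}

// Separable Gaussian filter, sigma per axis in voxels. Padding: replicate
// (zeropad = 0) or zero (zeropad = 1). sigma <= 0 along an axis skips it.
// [[Rcpp::export]]
NumericVector cpp_gauss3d(const NumericVector& data, const IntegerVector& dim,
                          const NumericVector& sigma, int zeropad = 0) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector cur = clone(data);
  NumericVector tmp(n);
  std::vector<double> k;
  const int nn[3] = {nx, ny, nz};
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma[axis];
    if (s <= 0) continue;
    gauss_kernel(s, k);
    int r = ((int)k.size() - 1) / 2;
    int na = nn[axis];
    // stride along this axis
    R_xlen_t stride = 1;
    for (int a = 0; a < axis; ++a) stride *= nn[a];
    // iterate over all lines along `axis`
    for (int kz = 0; kz < (axis == 2 ? 1 : nz); ++kz) {
      for (int jy = 0; jy < (axis == 1 ? 1 : ny); ++jy) {
        for (int ix = 0; ix < (axis == 0 ? 1 : nx); ++ix) {
          R_xlen_t base = vidx(ix, jy, kz, nx, ny);
          for (int t = 0; t < na; ++t) {
            double acc = 0.0;
            for (int u = -r; u <= r; ++u) {
              int tt = t + u;
              if (tt < 0 || tt >= na) {
                if (zeropad) continue;
                tt = (tt < 0) ? 0 : na - 1;
              }
              acc += k[u + r] * cur[base + stride * tt];
            }
            tmp[base + stride * t] = acc;
          }
        }
      }
    }
    std::copy(tmp.begin(), tmp.end(), cur.begin());
  }
  return cur;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher) on a sampled
// function f over positions x[i] = i*step.
// INF entries are clamped to a large finite sentinel so the lower-envelope
// recursion stays well-defined on partially-reached lines.
static const double DT_BIG = 1e20;

static void dt1d(const std::vector<double>& f, double step, std::vector<double>& d) {
  const int n = (int)f.size();
  d.assign(n, 0.0);
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int kk = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double qs = (double)q * step;
    double s;
    while (true) {
      double vs = (double)v[kk] * step;
      s = ((f[q] + qs * qs) - (f[v[kk]] + vs * vs)) / (2 * qs - 2 * vs);
      if (s <= z[kk]) { --kk; } else break;
    }
    ++kk;
    v[kk] = q;
    z[kk] = s;
    z[kk + 1] = std::numeric_limits<double>::infinity();
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    double qs = (double)q * step;
    while (z[kk + 1] < qs) ++kk;
    double vs = (double)v[kk] * step;
    d[q] = (qs - vs) * (qs - vs) + f[v[kk]];
  }
}

// Exact Euclidean distance (mm) from every voxel to the nearest voxel where
// mask != 0, honoring anisotropic spacing. All-zero mask -> all Inf.
// [[Rcpp::export]]
NumericVector cpp_edt3d(const IntegerVector& mask, const IntegerVector& dim,
                        const NumericVector& spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = mask[i] ? 0.0 : INF;
  std::vector<double> line, out;
  // x pass
  line.resize(nx); out.resize(nx);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = vidx(0, j, k, nx, ny);
      bool any = false;
      for (int i = 0; i < nx; ++i) { double v = d[base + i]; if (v < INF) any = true; line[i] = (v < INF) ? v : DT_BIG; }
      if (!any) continue;
      dt1d(line, spacing[0], out);
      for (int i = 0; i < nx; ++i) d[base + i] = out[i];
    }
  // y pass
  line.resize(ny); out.resize(ny);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = vidx(i, 0, k, nx, ny);
      bool any = false;
      for (int j = 0; j < ny; ++j) { double v = d[base + (R_xlen_t)j * nx]; if (v < INF) any = true; line[j] = (v < INF) ? v : DT_BIG; }
      if (!any) continue;
      dt1d(line, spacing[1], out);
      for (int j = 0; j < ny; ++j) d[base + (R_xlen_t)j * nx] = out[j];
    }
  // z pass
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  line.resize(nz); out.resize(nz);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = vidx(i, j, 0, nx, ny);
      bool any = false;
      for (int k = 0; k < nz; ++k) { double v = d[base + sz * k]; if (v < INF) any = true; line[k] = (v < INF) ? v : DT_BIG; }
      if (!any) continue;
      dt1d(line, spacing[2], out);
      for (int k = 0; k < nz; ++k) d[base + sz * k] = out[k];
    }
  for (R_xlen_t i = 0; i < n; ++i) d[i] = (d[i] >= DT_BIG / 2) ? R_PosInf : std::sqrt(d[i]);
  return d;
}

// Connected-component labeling of a binary volume (6- or 26-connectivity).
// Labels are 1..K in first-encounter order; background stays 0.
// [[Rcpp::export]]
IntegerVector cpp_label3d(const IntegerVector& mask, const IntegerVector& dim,
                          int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> di, dj, dk;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int m = std::abs(a) + std::abs(b) + std::abs(c);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        di.push_back(a); dj.push_back(b); dk.push_back(c);
      }
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t cur = q.front(); q.pop();
      int i = (int)(cur % nx);
      int j = (int)((cur / nx) % ny);
      int k = (int)(cur / ((R_xlen_t)nx * ny));
      for (size_t t = 0; t < di.size(); ++t) {
        int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        R_xlen_t v = vidx(ii, jj, kk, nx, ny);
        if (mask[v] && !lab[v]) { lab[v] = next; q.push(v); }
      }
    }
  }
  return lab;
}

// Central-difference gradient (per mm along voxel axes), replicate edges.
// Returns an n x 3 matrix.
// [[Rcpp::export]]
NumericMatrix cpp_gradient3d(const NumericVector& data, const IntegerVector& dim,
                             const NumericVector& spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericMatrix g(n, 3);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t c = vidx(i, j, k, nx, ny);
        int ip = std::min(i + 1, nx - 1), im = std::max(i - 1, 0);
        int jp = std::min(j + 1, ny - 1), jm = std::max(j - 1, 0);
        int kp = std::min(k + 1, nz - 1), km = std::max(k - 1, 0);
        g(c, 0) = (data[vidx(ip, j, k, nx, ny)] - data[vidx(im, j, k, nx, ny)]) /
                  ((ip - im) * spacing[0]);
        g(c, 1) = (data[vidx(i, jp, k, nx, ny)] - data[vidx(i, jm, k, nx, ny)]) /
                  ((jp - jm) * spacing[1]);
        g(c, 2) = (data[vidx(i, j, kp, nx, ny)] - data[vidx(i, j, km, nx, ny)]) /
                  ((kp - km) * spacing[2]);
      }
  return g;
}

// One-sided differences for upwind level-set schemes: returns n x 6 matrix
// with columns Dx-, Dx+, Dy-, Dy+, Dz-, Dz+ (per mm), replicate edges.
// [[Rcpp::export]]
NumericMatrix cpp_onesided3d(const NumericVector& data, const IntegerVector& dim,
                             const NumericVector& spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericMatrix g(n, 6);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t c = vidx(i, j, k, nx, ny);
        double v = data[c];
        int ip = std::min(i + 1, nx - 1), im = std::max(i - 1, 0);
        int jp = std::min(j + 1, ny - 1), jm = std::max(j - 1, 0);
        int kp = std::min(k + 1, nz - 1), km = std::max(k - 1, 0);
        g(c, 0) = (v - data[vidx(im, j, k, nx, ny)]) / spacing[0];
        g(c, 1) = (data[vidx(ip, j, k, nx, ny)] - v) / spacing[0];
        g(c, 2) = (v - data[vidx(i, jm, k, nx, ny)]) / spacing[1];
        g(c, 3) = (data[vidx(i, jp, k, nx, ny)] - v) / spacing[1];
        g(c, 4) = (v - data[vidx(i, j, km, nx, ny)]) / spacing[2];
        g(c, 5) = (data[vidx(i, j, kp, nx, ny)] - v) / spacing[2];
      }
  return g;
}

// Partial-volume joint histogram: for each sample point (continuous voxel
// coordinates in the moving image), the 8 trilinear weights are accumulated
// into the joint histogram row of the point's fixed-image bin, against the
// bin labels of the 8 corner voxels of the pre-binned moving image.
// fbin/mbin are 0-based bin indices; fbin < 0 marks an invalid sample.
// [[Rcpp::export]]
NumericMatrix cpp_pv_jhist(const IntegerVector& mbin, const IntegerVector& dim,
                           const NumericMatrix& pts, const IntegerVector& fbin,
                           int bins) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix counts(bins, bins);
  const R_xlen_t n = pts.nrow();
  for (R_xlen_t p = 0; p < n; ++p) {
    int fb = fbin[p];
    if (fb < 0) continue;
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (ISNAN(x) || ISNAN(y) || ISNAN(z)) continue;
    if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
      continue;
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 > nx - 2) i0 = nx - 2; if (j0 > ny - 2) j0 = ny - 2; if (k0 > nz - 2) k0 = nz - 2;
    if (nx == 1) i0 = 0; if (ny == 1) j0 = 0; if (nz == 1) k0 = 0;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1), k1 = std::min(k0 + 1, nz - 1);
    const int ii[2] = {i0, i1}, jj[2] = {j0, j1}, kk[2] = {k0, k1};
    const double wx[2] = {1 - fx, fx}, wy[2] = {1 - fy, fy}, wz[2] = {1 - fz, fz};
    for (int a = 0; a < 2; ++a)
      for (int b = 0; b < 2; ++b)
        for (int c = 0; c < 2; ++c) {
          double w = wx[a] * wy[b] * wz[c];
          if (w <= 0) continue;
          int mb = mbin[vidx(ii[a], jj[b], kk[c], nx, ny)];
          counts(fb, mb) += w;
        }
  }
  return counts;
}
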