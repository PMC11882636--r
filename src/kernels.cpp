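#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// 3D connected-component labeling on a logical volume stored in R array
// order, dim = (nz, ny, nx).  Labels are assigned 1..K in order of each
// component's first voxel in storage order.  connectivity: 6, 18 or 26.
// [[Rcpp::export]]
IntegerVector label3d_cpp(LogicalVector vol, IntegerVector dim, int connectivity) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);

  // neighbour offsets
  std::vector<int> dz, dy, dx;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int nn = std::abs(a) + std::abs(b) + std::abs(c);
        if (nn == 0) continue;
        if (connectivity == 6 && nn > 1) continue;
        if (connectivity == 18 && nn > 2) continue;
        dz.push_back(a); dy.push_back(b); dx.push_back(c);
      }
  const int noff = (int)dz.size();

  std::vector<R_xlen_t> queue;
  queue.reserve(1024);
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!vol[i] || lab[i]) continue;
    ++next;
    lab[i] = next;
    queue.clear();
    queue.push_back(i);
    size_t head = 0;
    while (head < queue.size()) {
      R_xlen_t cur = queue[head++];
      int x = (int)(cur / ((R_xlen_t)nz * ny));
      int rem = (int)(cur % ((R_xlen_t)nz * ny));
      int y = rem / nz;
      int z = rem % nz;
      for (int k = 0; k < noff; ++k) {
        int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        R_xlen_t j = (R_xlen_t)zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (vol[j] && !lab[j]) { lab[j] = next; queue.push_back(j); }
      }
    }
  }
  return lab;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher)
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Exact Euclidean distance (in pixels) from every pixel to the nearest
// zero-valued ("background") pixel of a binary matrix.  Background pixels
// get 0; if the matrix has no background, all distances are Inf.
// [[Rcpp::export]]
NumericMatrix edt2d_cpp(LogicalMatrix m) {
  const int nr = m.nrow(), nc = m.ncol();
  // large finite sentinel: infinities would produce Inf - Inf = NaN inside
  // the lower-envelope computation
  const double BIG = 1e20;
  NumericMatrix out(nr, nc);
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = m(i, j) ? BIG : 0.0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = out(i, j);
    dt1d(f, d, nr);
    for (int i = 0; i < nr; ++i) out(i, j) = d[i];
  }
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) f[j] = out(i, j);
    dt1d(f, d, nc);
    for (int j = 0; j < nc; ++j) out(i, j) = d[j];
  }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = (out(i, j) >= BIG) ?
        std::numeric_limits<double>::infinity() : std::sqrt(out(i, j));
  return out;
}

// Grayscale erosion/dilation by a non-flat hemispherical ("ball")
// structuring element of the given radius (pixels).  Out-of-image offsets
// do not constrain the extremum.
// [[Rcpp::export]]
NumericMatrix ball_morph_cpp(NumericMatrix img, double radius, bool erode) {
  const int nr = img.nrow(), nc = img.ncol();
  const int r = (int)std::floor(radius);
  std::vector<int> ody, odx;
  std::vector<double> oh;
  for (int a = -r; a <= r; ++a)
    for (int b = -r; b <= r; ++b) {
      double d2 = (double)a * a + (double)b * b;
      if (d2 <= radius * radius) {
        ody.push_back(a); odx.push_back(b);
        oh.push_back(std::sqrt(radius * radius - d2) - radius);
      }
    }
  const int noff = (int)ody.size();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double best = erode ? std::numeric_limits<double>::infinity()
                          : -std::numeric_limits<double>::infinity();
      for (int k = 0; k < noff; ++k) {
        int y = i + ody[k], x = j + odx[k];
        if (y < 0 || y >= nr || x < 0 || x >= nc) continue;
        // SE height is oh[k] + radius; the -radius shift keeps values in
        // range and cancels between erosion and dilation
        double v = erode ? img(y, x) - oh[k] : img(y, x) + oh[k];
        if (erode ? (v < best) : (v > best)) best = v;
      }
      out(i, j) = best;
    }
  return out;
}

// Convolve a 3D array (R storage order, dim = (nz, ny, nx)) with a 1D
// kernel along the given axis (0 = z, 1 = y, 2 = x), reflecting at the
// boundary.  Kernel length must be odd.
// [[Rcpp::export]]
NumericVector conv_axis_cpp(NumericVector arr, IntegerVector dim, int axis,
                            NumericVector kernel) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int kl = kernel.size(), half = kl / 2;
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector out(n);
  const int len = (axis == 0) ? nz : (axis == 1) ? ny : nx;
  const R_xlen_t stride = (axis == 0) ? 1 : (axis == 1) ? nz : (R_xlen_t)nz * ny;

  for (R_xlen_t i = 0; i < n; ++i) {
    int x = (int)(i / ((R_xlen_t)nz * ny));
    int rem = (int)(i % ((R_xlen_t)nz * ny));
    int y = rem / nz;
    int z = rem % nz;
    int pos = (axis == 0) ? z : (axis == 1) ? y : x;
    double acc = 0.0;
    for (int k = 0; k < kl; ++k) {
      int p = pos + k - half;
      if (p < 0) p = -p - 1;              // reflect
      if (p >= len) p = 2 * len - p - 1;
      acc += kernel[k] * arr[i + ((R_xlen_t)p - pos) * stride];
    }
    out[i] = acc;
  }
  return out;
}
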