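// Low-level image kernels. Images are R numeric matrices indexed (y, x).
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  // half-sample symmetric reflection: -1 -> 0, n -> n-1
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

static inline int clamp_idx(int i, int n) {
  return i < 0 ? 0 : (i >= n ? n - 1 : i);
}

// Separable convolution with a symmetric 1-D kernel, reflective padding.
// [[Rcpp::export]]
NumericMatrix cpp_conv_sep(const NumericMatrix& img, const NumericVector& k) {
  const int ny = img.nrow(), nx = img.ncol();
  const int m = k.size(), r = m / 2;
  NumericMatrix tmp(ny, nx), out(ny, nx);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      double s = 0.0;
      for (int j = 0; j < m; ++j) s += k[j] * img(reflect_idx(y + j - r, ny), x);
      tmp(y, x) = s;
    }
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      double s = 0.0;
      for (int j = 0; j < m; ++j) s += k[j] * tmp(y, reflect_idx(x + j - r, nx));
      out(y, x) = s;
    }
  return out;
}

// Grayscale erosion/dilation with an arbitrary (possibly non-flat)
// structuring element given as offset lists plus heights. Border pixels are
// replicated (clamped indexing).
// [[Rcpp::export]]
NumericMatrix cpp_morph(const NumericMatrix& img, const IntegerVector& dy,
                        const IntegerVector& dx, const NumericVector& h,
                        const bool erode) {
  const int ny = img.nrow(), nx = img.ncol(), m = dy.size();
  NumericMatrix out(ny, nx);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      double v = erode ? R_PosInf : R_NegInf;
      for (int j = 0; j < m; ++j) {
        const double z = img(clamp_idx(y + dy[j], ny), clamp_idx(x + dx[j], nx));
        if (erode) {
          const double c = z - h[j];
          if (c < v) v = c;
        } else {
          const double c = z + h[j];
          if (c > v) v = c;
        }
      }
      out(y, x) = v;
    }
  return out;
}

// 1-D squared distance transform (Felzenszwalb & Huttenlocher 2012).
// Background cost is a large finite sentinel rather than Inf so the parabola
// arithmetic stays well defined.
static const double DT_BIG = 1e20;

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -DT_BIG;
  z[1] = DT_BIG;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const int p = v[k];
    d[q] = (q - p) * (double)(q - p) + f[p];
  }
}

// Exact squared Euclidean distance to the nearest TRUE pixel.
// [[Rcpp::export]]
NumericMatrix cpp_edt_sq(const LogicalMatrix& mask) {
  const int ny = mask.nrow(), nx = mask.ncol();
  NumericMatrix out(ny, nx);
  std::vector<double> f(std::max(ny, nx)), d(std::max(ny, nx));
  // columns
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) f[y] = mask(y, x) ? 0.0 : DT_BIG;
    dt1d(f, d, ny);
    for (int y = 0; y < ny; ++y) out(y, x) = d[y];
  }
  // rows
  for (int y = 0; y < ny; ++y) {
    for (int x = 0; x < nx; ++x) f[x] = out(y, x);
    dt1d(f, d, nx);
    for (int x = 0; x < nx; ++x) out(y, x) = d[x];
  }
  return out;
}

// Connected-component labelling (4- or 8-connectivity). Labels are assigned
// in column-major scan order, so the component containing the first-scanned
// pixel gets label 1 (deterministic tie-breaking downstream).
// [[Rcpp::export]]
IntegerMatrix cpp_label(const LogicalMatrix& mask, const int connectivity) {
  const int ny = mask.nrow(), nx = mask.ncol();
  IntegerMatrix lab(ny, nx);
  const int ndy8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int ndx8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      if (!mask(y, x) || lab(y, x) != 0) continue;
      ++next;
      lab(y, x) = next;
      q.push(std::make_pair(y, x));
      while (!q.empty()) {
        const std::pair<int, int> p = q.front();
        q.pop();
        for (int j = 0; j < nn; ++j) {
          const int yy = p.first + ndy8[j], xx = p.second + ndx8[j];
          if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
          if (mask(yy, xx) && lab(yy, xx) == 0) {
            lab(yy, xx) = next;
            q.push(std::make_pair(yy, xx));
          }
        }
      }
    }
  return lab;
}

// Grayscale morphological reconstruction by dilation of `marker` under
// `mask` (marker <= mask elementwise), hybrid raster/queue algorithm
// (Vincent 1993).
// [[Rcpp::export]]
NumericMatrix cpp_reconstruct(const NumericMatrix& marker,
                              const NumericMatrix& mask,
                              const int connectivity) {
  const int ny = marker.nrow(), nx = marker.ncol();
  NumericMatrix J(ny, nx);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      J(y, x) = std::min(marker(y, x), mask(y, x));

  const int ndy8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int ndx8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 8) ? 8 : 4;

  // forward raster scan (neighbours preceding in column-major order)
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      double v = J(y, x);
      for (int j = 0; j < nn; ++j) {
        const int yy = y + ndy8[j], xx = x + ndx8[j];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        if (xx < x || (xx == x && yy < y)) v = std::max(v, J(yy, xx));
      }
      J(y, x) = std::min(v, mask(y, x));
    }
  // backward raster scan + queue seeding
  std::queue<std::pair<int, int> > q;
  for (int x = nx - 1; x >= 0; --x)
    for (int y = ny - 1; y >= 0; --y) {
      double v = J(y, x);
      for (int j = 0; j < nn; ++j) {
        const int yy = y + ndy8[j], xx = x + ndx8[j];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        if (xx > x || (xx == x && yy > y)) v = std::max(v, J(yy, xx));
      }
      J(y, x) = std::min(v, mask(y, x));
      for (int j = 0; j < nn; ++j) {
        const int yy = y + ndy8[j], xx = x + ndx8[j];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        if ((xx > x || (xx == x && yy > y)) && J(yy, xx) < J(y, x) &&
            J(yy, xx) < mask(yy, xx)) {
          q.push(std::make_pair(y, x));
          break;
        }
      }
    }
  while (!q.empty()) {
    const std::pair<int, int> p = q.front();
    q.pop();
    for (int j = 0; j < nn; ++j) {
      const int yy = p.first + ndy8[j], xx = p.second + ndx8[j];
      if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      if (J(yy, xx) < J(p.first, p.second) && mask(yy, xx) != J(yy, xx)) {
        J(yy, xx) = std::min(J(p.first, p.second), mask(yy, xx));
        q.push(std::make_pair(yy, xx));
      }
    }
  }
  return J;
}
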