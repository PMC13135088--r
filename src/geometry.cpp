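#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
using namespace Rcpp;

// 1-D squared distance transform (Felzenszwalb & Huttenlocher) along a line of
// squared costs f, with sample step `step` (mm). Writes result into d.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 double step) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double qq = (double)q * step, vv;
    double s;
    while (true) {
      vv = (double)v[k] * step;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2.0 * qq - 2.0 * vv);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qq = (double)q * step;
    while (z[k + 1] < qq) ++k;
    double vv = (double)v[k] * step;
    d[q] = (qq - vv) * (qq - vv) + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  // Euclidean distance (mm) from every voxel to the nearest TRUE voxel of mask.
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> d((size_t)n);
  const double INF = 1e20;
  for (R_xlen_t i = 0; i < n; ++i) d[(size_t)i] = mask[i] ? 0.0 : INF;

  std::vector<double> line, out;
  // pass along x
  line.resize(nx); out.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) line[x] = d[(size_t)(base + x)];
      dt1d(line, out, spacing[0]);
      for (int x = 0; x < nx; ++x) d[(size_t)(base + x)] = out[x];
    }
  // pass along y
  line.resize(ny); out.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) line[y] = d[(size_t)(base + (R_xlen_t)y * nx)];
      dt1d(line, out, spacing[1]);
      for (int y = 0; y < ny; ++y) d[(size_t)(base + (R_xlen_t)y * nx)] = out[y];
    }
  // pass along z
  line.resize(nz); out.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; ++z) line[z] = d[(size_t)(base + (R_xlen_t)z * nx * ny)];
      dt1d(line, out, spacing[2]);
      for (int z = 0; z < nz; ++z) d[(size_t)(base + (R_xlen_t)z * nx * ny)] = out[z];
    }

  NumericVector res(n);
  for (R_xlen_t i = 0; i < n; ++i)
    res[i] = std::sqrt(d[(size_t)i]);
  res.attr("dim") = dim;
  return res;
}

// [[Rcpp::export(name = ".label3d")]]
IntegerVector label3d(LogicalVector mask, IntegerVector dim) {
  // 6-connected component labelling; labels 1..k in discovery order, 0 = background.
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<R_xlen_t> q;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    q.push(i);
    while (!q.empty()) {
      R_xlen_t c = q.front(); q.pop();
      int z = (int)(c / sz), r = (int)(c % sz);
      int y = r / nx, x = r % nx;
      R_xlen_t nb[6];
      int k = 0;
      if (x > 0) nb[k++] = c - sx;
      if (x < nx - 1) nb[k++] = c + sx;
      if (y > 0) nb[k++] = c - sy;
      if (y < ny - 1) nb[k++] = c + sy;
      if (z > 0) nb[k++] = c - sz;
      if (z < nz - 1) nb[k++] = c + sz;
      for (int j = 0; j < k; ++j) {
        R_xlen_t p = nb[j];
        if (mask[p] && lab[p] == 0) { lab[p] = next; q.push(p); }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}
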