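#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// 6-connected component labelling of a 3-D logical array via BFS.
// Returns an integer array of the same dimensions: 0 outside the mask,
// 1..k component ids (1 = first component encountered in array order).
// [[Rcpp::export(name = ".cc_label3d")]]
IntegerVector cc_label3d(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  lab.attr("dim") = dims;
  int next_label = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next_label;
    lab[s] = next_label;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t v = q.front(); q.pop();
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((R_xlen_t)nx * ny));
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = (R_xlen_t)xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[w] && lab[w] == 0) {
          lab[w] = next_label;
          q.push(w);
        }
      }
    }
  }
  return lab;
}

static LogicalVector dilate_once(const LogicalVector& m, int nx, int ny,
                                 int nz) {
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, false);
  for (R_xlen_t v = 0; v < n; ++v) {
    if (!m[v]) continue;
    int x = (int)(v % nx);
    int y = (int)((v / nx) % ny);
    int z = (int)(v / ((R_xlen_t)nx * ny));
    out[v] = true;
    const int dx[6] = {-1, 1, 0, 0, 0, 0};
    const int dy[6] = {0, 0, -1, 1, 0, 0};
    const int dz[6] = {0, 0, 0, 0, -1, 1};
    for (int k = 0; k < 6; ++k) {
      int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      out[(R_xlen_t)xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)] = true;
    }
  }
  return out;
}

static LogicalVector erode_once(const LogicalVector& m, int nx, int ny,
                                int nz) {
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, false);
  for (R_xlen_t v = 0; v < n; ++v) {
    if (!m[v]) continue;
    int x = (int)(v % nx);
    int y = (int)((v / nx) % ny);
    int z = (int)(v / ((R_xlen_t)nx * ny));
    bool keep = true;
    const int dx[6] = {-1, 1, 0, 0, 0, 0};
    const int dy[6] = {0, 0, -1, 1, 0, 0};
    const int dz[6] = {0, 0, 0, 0, -1, 1};
    for (int k = 0; k < 6 && keep; ++k) {
      int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;  // out-of-bounds neighbours do not erode the border
      if (!m[(R_xlen_t)xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)])
        keep = false;
    }
    out[v] = keep;
  }
  return out;
}

// Morphological closing (dilation then erosion, 6-neighbourhood cross
// structuring element applied `iter` times each way).
// [[Rcpp::export(name = ".binary_close3d")]]
LogicalVector binary_close3d(LogicalVector mask, IntegerVector dims,
                             int iter) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector m = clone(mask);
  for (int i = 0; i < iter; ++i) m = dilate_once(m, nx, ny, nz);
  for (int i = 0; i < iter; ++i) m = erode_once(m, nx, ny, nz);
  m.attr("dim") = dims;
  return m;
}
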