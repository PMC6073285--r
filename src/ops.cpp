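#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 2D median filter, (2r+1)x(2r+1) window, borders by edge replication.
// [[Rcpp::export]]
NumericMatrix cpp_median_filter(NumericMatrix img, int radius) {
  int nr = img.nrow(), nc = img.ncol();
  if (radius <= 0) return clone(img);
  NumericMatrix out(nr, nc);
  int w = 2 * radius + 1;
  int n = w * w, mid = n / 2;  // n odd -> true median
  std::vector<double> buf(n);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int k = 0;
      for (int dj = -radius; dj <= radius; ++dj) {
        int jj = std::min(std::max(j + dj, 0), nc - 1);
        for (int di = -radius; di <= radius; ++di) {
          int ii = std::min(std::max(i + di, 0), nr - 1);
          buf[k++] = img(ii, jj);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      out(i, j) = buf[mid];
    }
  }
  return out;
}

// Neighbourhood offsets for 6/18/26-connectivity in (z, y, x) index space.
static void conn_offsets(int connectivity, std::vector<int>& dz,
                         std::vector<int>& dy, std::vector<int>& dx) {
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int s = std::abs(a) + std::abs(b) + std::abs(c);
        if (s == 0) continue;
        if (connectivity == 6 && s > 1) continue;
        if (connectivity == 18 && s > 2) continue;
        dz.push_back(a); dy.push_back(b); dx.push_back(c);
      }
}

// Connected-component labeling on a (nz, ny, nx) logical grid stored in R
// column-major order (z fastest). Labels are assigned in order of the first
// voxel of each component in storage order, so the result is deterministic.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector labels(n, 0);
  std::vector<int> dz, dy, dx;
  conn_offsets(connectivity, dz, dy, dx);
  int nofs = dz.size();
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++next;
    labels[start] = next;
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int z = v % nz;
      int y = (v / nz) % ny;
      int x = v / ((R_xlen_t)nz * ny);
      for (int o = 0; o < nofs; ++o) {
        int zz = z + dz[o], yy = y + dy[o], xx = x + dx[o];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        R_xlen_t u = (R_xlen_t)xx * nz * ny + (R_xlen_t)yy * nz + zz;
        if (mask[u] && labels[u] == 0) {
          labels[u] = next;
          stack.push_back(u);
        }
      }
    }
  }
  labels.attr("dim") = dim;
  return labels;
}

// Per-object voxel counts, 1-based bounding boxes and per-axis edge contact.
// [[Rcpp::export]]
List cpp_object_stats(IntegerVector labels, IntegerVector dim, int nlab) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector size(nlab, 0);
  IntegerMatrix bbox(nlab, 6);  // z0 z1 y0 y1 x0 x1
  LogicalMatrix touch(nlab, 3); // z, y, x face contact
  for (int i = 0; i < nlab; ++i) {
    bbox(i, 0) = nz + 1; bbox(i, 1) = 0;
    bbox(i, 2) = ny + 1; bbox(i, 3) = 0;
    bbox(i, 4) = nx + 1; bbox(i, 5) = 0;
  }
  for (R_xlen_t v = 0; v < n; ++v) {
    int lab = labels[v];
    if (lab == 0) continue;
    int i = lab - 1;
    int z = v % nz;
    int y = (v / nz) % ny;
    int x = v / ((R_xlen_t)nz * ny);
    size[i]++;
    if (z + 1 < bbox(i, 0)) bbox(i, 0) = z + 1;
    if (z + 1 > bbox(i, 1)) bbox(i, 1) = z + 1;
    if (y + 1 < bbox(i, 2)) bbox(i, 2) = y + 1;
    if (y + 1 > bbox(i, 3)) bbox(i, 3) = y + 1;
    if (x + 1 < bbox(i, 4)) bbox(i, 4) = x + 1;
    if (x + 1 > bbox(i, 5)) bbox(i, 5) = x + 1;
    if (z == 0 || z == nz - 1) touch(i, 0) = true;
    if (y == 0 || y == ny - 1) touch(i, 1) = true;
    if (x == 0 || x == nx - 1) touch(i, 2) = true;
  }
  return List::create(_["size"] = size, _["bbox"] = bbox,
                      _["touch"] = touch);
}

// Border voxels of object `id`: voxels with >= 1 face-neighbour (6-conn)
// outside the object (out-of-grid counts as outside). Returns 1-based
// (z, y, x) rows.
// [[Rcpp::export]]
IntegerMatrix cpp_border_voxels(IntegerVector labels, IntegerVector dim,
                                int id) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  static const int fz[6] = {-1, 1, 0, 0, 0, 0};
  static const int fy[6] = {0, 0, -1, 1, 0, 0};
  static const int fx[6] = {0, 0, 0, 0, -1, 1};
  std::vector<int> bz, by, bx;
  for (R_xlen_t v = 0; v < n; ++v) {
    if (labels[v] != id) continue;
    int z = v % nz;
    int y = (v / nz) % ny;
    int x = v / ((R_xlen_t)nz * ny);
    bool border = false;
    for (int o = 0; o < 6 && !border; ++o) {
      int zz = z + fz[o], yy = y + fy[o], xx = x + fx[o];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) {
        border = true;
      } else {
        R_xlen_t u = (R_xlen_t)xx * nz * ny + (R_xlen_t)yy * nz + zz;
        if (labels[u] != id) border = true;
      }
    }
    if (border) { bz.push_back(z + 1); by.push_back(y + 1); bx.push_back(x + 1); }
  }
  int m = bz.size();
  IntegerMatrix out(m, 3);
  for (int i = 0; i < m; ++i) {
    out(i, 0) = bz[i]; out(i, 1) = by[i]; out(i, 2) = bx[i];
  }
  return out;
}

// Minimum anisotropic Euclidean distance between voxel centres of two voxel
// sets given as 1-based (z, y, x) rows; vox = (dz, dy, dx) in micrometres.
// [[Rcpp::export]]
double cpp_min_pair_dist(IntegerMatrix a, IntegerMatrix b,
                         NumericVector vox) {
  double dz = vox[0], dy = vox[1], dx = vox[2];
  double best = R_PosInf;
  int na = a.nrow(), nb = b.nrow();
  for (int i = 0; i < na; ++i) {
    double az = a(i, 0) * dz, ay = a(i, 1) * dy, ax = a(i, 2) * dx;
    for (int j = 0; j < nb; ++j) {
      double z = az - b(j, 0) * dz;
      double y = ay - b(j, 1) * dy;
      double x = ax - b(j, 2) * dx;
      double d2 = z * z + y * y + x * x;
      if (d2 < best) {
        best = d2;
        if (best == 0.0) return 0.0;
      }
    }
  }
  return std::sqrt(best);
}

// Separable Gaussian blur of a (nz, ny, nx) grid; sigma per axis in voxel
// units; borders by edge replication; kernel radius ceil(3 sigma).
// [[Rcpp::export]]
NumericVector cpp_gaussian_blur3d(NumericVector arr, IntegerVector dim,
                                  NumericVector sigma) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<double> cur(arr.begin(), arr.end()), tmp(n);
  int strides[3] = {1, nz, nz * ny};
  int extent[3] = {nz, ny, nx};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> k(2 * r + 1);
    double sum = 0;
    for (int i = -r; i <= r; ++i) {
      k[i + r] = std::exp(-0.5 * i * i / (s * s));
      sum += k[i + r];
    }
    for (double& w : k) w /= sum;
    int len = extent[ax];
    R_xlen_t stride = strides[ax];
    // iterate over all lines along axis ax
    R_xlen_t nlines = n / len;
    int oa = (ax + 1) % 3, ob = (ax + 2) % 3;
    for (R_xlen_t ln = 0; ln < nlines; ++ln) {
      R_xlen_t ia = ln % extent[oa], ib = ln / extent[oa];
      R_xlen_t base = ia * strides[oa] + ib * strides[ob];
      for (int p = 0; p < len; ++p) {
        double acc = 0;
        for (int q = -r; q <= r; ++q) {
          int pp = std::min(std::max(p + q, 0), len - 1);
          acc += k[q + r] * cur[base + (R_xlen_t)pp * stride];
        }
        tmp[base + (R_xlen_t)p * stride] = acc;
      }
    }
    std::swap(cur, tmp);
  }
  NumericVector out(cur.begin(), cur.end());
  out.attr("dim") = dim;
  return out;
}

// Morphological dilation of a logical matrix with a (2r+1)^2 square
// structuring element (Chebyshev ball), clipped at image bounds.
// [[Rcpp::export]]
LogicalMatrix cpp_box_dilate(LogicalMatrix m, int radius) {
  int nr = m.nrow(), nc = m.ncol();
  LogicalMatrix mid(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      bool v = false;
      for (int d = -radius; d <= radius && !v; ++d) {
        int ii = i + d;
        if (ii >= 0 && ii < nr && m(ii, j)) v = true;
      }
      mid(i, j) = v;
    }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      bool v = false;
      for (int d = -radius; d <= radius && !v; ++d) {
        int jj = j + d;
        if (jj >= 0 && jj < nc && mid(i, jj)) v = true;
      }
      out(i, j) = v;
    }
  return out;
}
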