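#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Gaussian-sum density: each atom stamps C * m * exp(-||y - x||^2 / (2 s^2))
// onto the grid, truncated at cutoff_mult * s.
// [[Rcpp::export(name = ".density_sum_cpp")]]
NumericVector density_sum_cpp(NumericMatrix pos, NumericVector mass,
                              NumericVector origin, double spacing,
                              IntegerVector dims, double sigma, double coefC,
                              double cutoff_mult = 3.0) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(static_cast<R_xlen_t>(nx) * ny * nz);
  const double cut = cutoff_mult * sigma;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const int n = pos.nrow();
  for (int a = 0; a < n; ++a) {
    const double x = pos(a, 0), y = pos(a, 1), z = pos(a, 2);
    const double cm = coefC * mass[a];
    int i0 = (int)std::ceil((x - cut - origin[0]) / spacing);
    int i1 = (int)std::floor((x + cut - origin[0]) / spacing);
    int j0 = (int)std::ceil((y - cut - origin[1]) / spacing);
    int j1 = (int)std::floor((y + cut - origin[1]) / spacing);
    int k0 = (int)std::ceil((z - cut - origin[2]) / spacing);
    int k1 = (int)std::floor((z + cut - origin[2]) / spacing);
    if (i0 < 0) i0 = 0; if (i1 > nx - 1) i1 = nx - 1;
    if (j0 < 0) j0 = 0; if (j1 > ny - 1) j1 = ny - 1;
    if (k0 < 0) k0 = 0; if (k1 > nz - 1) k1 = nz - 1;
    for (int k = k0; k <= k1; ++k) {
      const double dz = origin[2] + k * spacing - z;
      for (int j = j0; j <= j1; ++j) {
        const double dy = origin[1] + j * spacing - y;
        const double d2yz = dy * dy + dz * dz;
        R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
        for (int i = i0; i <= i1; ++i) {
          const double dx = origin[0] + i * spacing - x;
          const double d2 = dx * dx + d2yz;
          if (d2 <= cut * cut) out[base + i] += cm * std::exp(-d2 * inv2s2);
        }
      }
    }
  }
  return out;
}

static void blur_axis(const std::vector<double> &in, std::vector<double> &out,
                      int nx, int ny, int nz, int axis,
                      const std::vector<double> &kern) {
  const int r = (int)kern.size() / 2;
  const int dim[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  const int n_axis = dim[axis];
  const R_xlen_t s = stride[axis];
  // iterate over all lines along `axis`
  int oa = (axis + 1) % 3, ob = (axis + 2) % 3;
  for (int b = 0; b < dim[ob]; ++b) {
    for (int a = 0; a < dim[oa]; ++a) {
      R_xlen_t off = (R_xlen_t)a * stride[oa] + (R_xlen_t)b * stride[ob];
      for (int i = 0; i < n_axis; ++i) {
        double acc = 0.0;
        for (int t = -r; t <= r; ++t) {
          int ii = i + t;
          if (ii < 0 || ii >= n_axis) continue; // zero padding
          acc += kern[t + r] * in[off + (R_xlen_t)ii * s];
        }
        out[off + (R_xlen_t)i * s] = acc;
      }
    }
  }
}

// Separable Gaussian blur, sigma in voxel units, zero padding at edges.
// [[Rcpp::export(name = ".blur3_cpp")]]
NumericVector blur3_cpp(NumericVector vals, IntegerVector dims,
                        double sigma_vox) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (sigma_vox <= 0) return clone(vals);
  int r = (int)std::ceil(4.0 * sigma_vox);
  std::vector<double> kern(2 * r + 1);
  double ksum = 0.0;
  for (int t = -r; t <= r; ++t) {
    kern[t + r] = std::exp(-0.5 * t * t / (sigma_vox * sigma_vox));
    ksum += kern[t + r];
  }
  for (size_t i = 0; i < kern.size(); ++i) kern[i] /= ksum;
  std::vector<double> buf1(vals.begin(), vals.end()), buf2(n);
  blur_axis(buf1, buf2, nx, ny, nz, 0, kern);
  blur_axis(buf2, buf1, nx, ny, nz, 1, kern);
  blur_axis(buf1, buf2, nx, ny, nz, 2, kern);
  NumericVector out(n);
  std::copy(buf2.begin(), buf2.end(), out.begin());
  return out;
}

// Trilinear interpolation; points outside the grid evaluate to 0.
// [[Rcpp::export(name = ".trilinear_cpp")]]
NumericVector trilinear_cpp(NumericVector vals, IntegerVector dims,
                            NumericVector origin, double spacing,
                            NumericMatrix pts) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = pts.nrow();
  NumericVector out(n);
  for (int q = 0; q < n; ++q) {
    double fx = (pts(q, 0) - origin[0]) / spacing;
    double fy = (pts(q, 1) - origin[1]) / spacing;
    double fz = (pts(q, 2) - origin[2]) / spacing;
    if (fx < 0 || fy < 0 || fz < 0 || fx > nx - 1 || fy > ny - 1 ||
        fz > nz - 1) {
      out[q] = 0.0;
      continue;
    }
    int i = (int)std::floor(fx), j = (int)std::floor(fy),
        k = (int)std::floor(fz);
    if (i == nx - 1) i--; if (j == ny - 1) j--; if (k == nz - 1) k--;
    double tx = fx - i, ty = fy - j, tz = fz - k;
    double v = 0.0;
    for (int dk = 0; dk <= 1; ++dk)
      for (int dj = 0; dj <= 1; ++dj)
        for (int di = 0; di <= 1; ++di) {
          double w = (di ? tx : 1 - tx) * (dj ? ty : 1 - ty) *
                     (dk ? tz : 1 - tz);
          v += w * vals[(R_xlen_t)(k + dk) * nx * ny +
                        (R_xlen_t)(j + dj) * nx + (i + di)];
        }
    out[q] = v;
  }
  return out;
}

struct BinGrid {
  double lo[3];
  double bin;
  int nb[3];
  std::vector<int> start;  // CSR offsets per cell
  std::vector<int> idx;    // point indices ordered by cell
  void build(const NumericMatrix &pts, double bin_size) {
    bin = bin_size;
    const int n = pts.nrow();
    double hi[3];
    for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) {
        if (pts(i, d) < lo[d]) lo[d] = pts(i, d);
        if (pts(i, d) > hi[d]) hi[d] = pts(i, d);
      }
    for (int d = 0; d < 3; ++d) {
      nb[d] = std::max(1, (int)std::floor((hi[d] - lo[d]) / bin) + 1);
    }
    R_xlen_t ncell = (R_xlen_t)nb[0] * nb[1] * nb[2];
    start.assign(ncell + 1, 0);
    std::vector<int> cell(n);
    for (int i = 0; i < n; ++i) {
      int c[3];
      for (int d = 0; d < 3; ++d) {
        c[d] = (int)std::floor((pts(i, d) - lo[d]) / bin);
        if (c[d] < 0) c[d] = 0;
        if (c[d] >= nb[d]) c[d] = nb[d] - 1;
      }
      cell[i] = (c[2] * nb[1] + c[1]) * nb[0] + c[0];
      start[cell[i] + 1]++;
    }
    for (R_xlen_t c = 0; c < ncell; ++c) start[c + 1] += start[c];
    idx.assign(n, 0);
    std::vector<int> fill(start.begin(), start.end() - 1);
    for (int i = 0; i < n; ++i) idx[fill[cell[i]]++] = i;
  }
  int cell_of(double v, int d) const {
    return (int)std::floor((v - lo[d]) / bin);
  }
};

// Exact nearest neighbour with grid acceleration; ties broken by lowest
// (1-based) point index, matching an exhaustive scan.
// [[Rcpp::export(name = ".nearest_point_cpp")]]
IntegerVector nearest_point_cpp(NumericMatrix pts, NumericMatrix queries,
                                double bin = 5.0) {
  const int n = pts.nrow(), m = queries.nrow();
  IntegerVector out(m);
  if (n == 0) stop("empty point set");
  BinGrid g;
  g.build(pts, bin);
  const int rmax = std::max(std::max(g.nb[0], g.nb[1]), g.nb[2]) + 2;
  for (int q = 0; q < m; ++q) {
    const double qx = queries(q, 0), qy = queries(q, 1), qz = queries(q, 2);
    int c[3] = {g.cell_of(qx, 0), g.cell_of(qy, 1), g.cell_of(qz, 2)};
    double best2 = R_PosInf;
    int besti = -1;
    for (int r = 0;; ++r) {
      double lb = (r - 1) * g.bin;  // lower bound on distance to ring r
      if (besti >= 0 && lb > 0 && lb * lb > best2) break;
      if (r > rmax + std::max(std::max(std::abs(c[0]), std::abs(c[1])),
                              std::abs(c[2]))) break;
      bool any_cell = false;
      int klo = c[2] - r, khi = c[2] + r;
      for (int k = klo; k <= khi; ++k) {
        if (k < 0 || k >= g.nb[2]) continue;
        for (int j = c[1] - r; j <= c[1] + r; ++j) {
          if (j < 0 || j >= g.nb[1]) continue;
          for (int i = c[0] - r; i <= c[0] + r; ++i) {
            if (i < 0 || i >= g.nb[0]) continue;
            // only the shell at Chebyshev distance r
            int ch = std::max(std::max(std::abs(i - c[0]), std::abs(j - c[1])),
                              std::abs(k - c[2]));
            if (ch != r) continue;
            any_cell = true;
            R_xlen_t cc = ((R_xlen_t)k * g.nb[1] + j) * g.nb[0] + i;
            for (int t = g.start[cc]; t < g.start[cc + 1]; ++t) {
              int p = g.idx[t];
              double dx = pts(p, 0) - qx, dy = pts(p, 1) - qy,
                     dz = pts(p, 2) - qz;
              double d2 = dx * dx + dy * dy + dz * dz;
              if (d2 < best2 || (d2 == best2 && p < besti)) {
                best2 = d2;
                besti = p;
              }
            }
          }
        }
      }
      if (!any_cell && besti >= 0 && (r - 1) * g.bin > std::sqrt(best2))
        break;
    }
    out[q] = besti + 1;
  }
  return out;
}

// All unordered pairs with distance < cutoff (strict) where at least one
// member is flagged. Returns a 2-column matrix of 1-based indices, i < j.
// [[Rcpp::export(name = ".pairs_within_cpp")]]
IntegerMatrix pairs_within_cpp(NumericMatrix pts, double cutoff,
                               LogicalVector flagged) {
  const int n = pts.nrow();
  std::vector<int> pi, pj;
  if (n > 1) {
    BinGrid g;
    g.build(pts, cutoff);
    const double cut2 = cutoff * cutoff;
    for (int a = 0; a < n; ++a) {
      int c[3] = {g.cell_of(pts(a, 0), 0), g.cell_of(pts(a, 1), 1),
                  g.cell_of(pts(a, 2), 2)};
      for (int k = std::max(0, c[2] - 1);
           k <= std::min(g.nb[2] - 1, c[2] + 1); ++k)
        for (int j = std::max(0, c[1] - 1);
             j <= std::min(g.nb[1] - 1, c[1] + 1); ++j)
          for (int i = std::max(0, c[0] - 1);
               i <= std::min(g.nb[0] - 1, c[0] + 1); ++i) {
            R_xlen_t cc = ((R_xlen_t)k * g.nb[1] + j) * g.nb[0] + i;
            for (int t = g.start[cc]; t < g.start[cc + 1]; ++t) {
              int b = g.idx[t];
              if (b <= a) continue;
              if (!(flagged[a] || flagged[b])) continue;
              double dx = pts(b, 0) - pts(a, 0), dy = pts(b, 1) - pts(a, 1),
                     dz = pts(b, 2) - pts(a, 2);
              if (dx * dx + dy * dy + dz * dz < cut2) {
                pi.push_back(a + 1);
                pj.push_back(b + 1);
              }
            }
          }
    }
  }
  IntegerMatrix out(pi.size(), 2);
  for (size_t t = 0; t < pi.size(); ++t) {
    out(t, 0) = pi[t];
    out(t, 1) = pj[t];
  }
  return out;
}

// Jacobi eigen decomposition of a symmetric 3x3 matrix; returns the
// eigenvector of the smallest eigenvalue in v.
static void smallest_eigvec3(double m[3][3], double v[3]) {
  double a[3][3];
  double q[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) a[i][j] = m[i][j];
  for (int sweep = 0; sweep < 50; ++sweep) {
    double off = std::fabs(a[0][1]) + std::fabs(a[0][2]) + std::fabs(a[1][2]);
    if (off < 1e-15) break;
    for (int p = 0; p < 2; ++p)
      for (int r = p + 1; r < 3; ++r) {
        if (std::fabs(a[p][r]) < 1e-18) continue;
        double theta = (a[r][r] - a[p][p]) / (2.0 * a[p][r]);
        double t = (theta >= 0 ? 1.0 : -1.0) /
                   (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
        double cth = 1.0 / std::sqrt(t * t + 1.0), s = t * cth;
        for (int k = 0; k < 3; ++k) {
          double akp = a[k][p], akr = a[k][r];
          a[k][p] = cth * akp - s * akr;
          a[k][r] = s * akp + cth * akr;
        }
        for (int k = 0; k < 3; ++k) {
          double apk = a[p][k], ark = a[r][k];
          a[p][k] = cth * apk - s * ark;
          a[r][k] = s * apk + cth * ark;
        }
        for (int k = 0; k < 3; ++k) {
          double qkp = q[k][p], qkr = q[k][r];
          q[k][p] = cth * qkp - s * qkr;
          q[k][r] = s * qkp + cth * qkr;
        }
      }
  }
  int imin = 0;
  if (a[1][1] < a[imin][imin]) imin = 1;
  if (a[2][2] < a[imin][imin]) imin = 2;
  for (int k = 0; k < 3; ++k) v[k] = q[k][imin];
}

// Per-point least-squares plane normal from all points within `radius`
// (the point itself included). Points with fewer than 3 neighbours get NA.
// [[Rcpp::export(name = ".plane_normals_cpp")]]
List plane_normals_cpp(NumericMatrix pts, double radius) {
  const int n = pts.nrow();
  NumericMatrix normals(n, 3);
  IntegerVector nnb(n);
  BinGrid g;
  g.build(pts, radius);
  const double r2 = radius * radius;
  std::vector<int> nb;
  for (int a = 0; a < n; ++a) {
    nb.clear();
    int c[3] = {g.cell_of(pts(a, 0), 0), g.cell_of(pts(a, 1), 1),
                g.cell_of(pts(a, 2), 2)};
    double mean[3] = {0, 0, 0};
    for (int k = std::max(0, c[2] - 1); k <= std::min(g.nb[2] - 1, c[2] + 1);
         ++k)
      for (int j = std::max(0, c[1] - 1);
           j <= std::min(g.nb[1] - 1, c[1] + 1); ++j)
        for (int i = std::max(0, c[0] - 1);
             i <= std::min(g.nb[0] - 1, c[0] + 1); ++i) {
          R_xlen_t cc = ((R_xlen_t)k * g.nb[1] + j) * g.nb[0] + i;
          for (int t = g.start[cc]; t < g.start[cc + 1]; ++t) {
            int b = g.idx[t];
            double dx = pts(b, 0) - pts(a, 0), dy = pts(b, 1) - pts(a, 1),
                   dz = pts(b, 2) - pts(a, 2);
            if (dx * dx + dy * dy + dz * dz <= r2) {
              nb.push_back(b);
              mean[0] += pts(b, 0);
              mean[1] += pts(b, 1);
              mean[2] += pts(b, 2);
            }
          }
        }
    nnb[a] = (int)nb.size();
    if ((int)nb.size() < 3) {
      normals(a, 0) = NA_REAL;
      normals(a, 1) = NA_REAL;
      normals(a, 2) = NA_REAL;
      continue;
    }
    for (int d = 0; d < 3; ++d) mean[d] /= nb.size();
    double cov[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
    for (size_t t = 0; t < nb.size(); ++t) {
      double d[3] = {pts(nb[t], 0) - mean[0], pts(nb[t], 1) - mean[1],
                     pts(nb[t], 2) - mean[2]};
      for (int u = 0; u < 3; ++u)
        for (int w = 0; w < 3; ++w) cov[u][w] += d[u] * d[w];
    }
    double v[3];
    smallest_eigvec3(cov, v);
    double nrm = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
    for (int d = 0; d < 3; ++d) normals(a, d) = v[d] / nrm;
  }
  return List::create(_["normals"] = normals, _["n_neighbours"] = nnb);
}
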