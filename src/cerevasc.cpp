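// Low-level 3-D image primitives: exact Euclidean distance transform,
// connected-component labeling, threshold-gated region growing, GGMRF/ICM
// smoothing sweeps, separable Gaussian filtering, and iso-surface extraction
// by tetrahedral decomposition.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------------------
// 1-D squared distance transform (Felzenszwalb & Huttenlocher), sample
// spacing w. f holds squared distances on entry; overwritten in place.
static void dt1d(std::vector<double> &f, double w) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1), d(n);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    double s;
    for (;;) {
      double xq = q * w, xv = v[k] * w;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k] && k > 0) { k--; } else break;
    }
    if (s <= z[k] && k == 0) {
      v[0] = q;
    } else {
      k++;
      v[k] = q;
      z[k] = s;
      z[k + 1] = INF;
    }
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double xq = q * w;
    while (z[k + 1] < xq) k++;
    double dx = xq - v[k] * w;
    d[q] = dx * dx + f[v[k]];
  }
  for (int q = 0; q < n; q++) f[q] = d[q];
}

// Squared Euclidean distance (mm^2) from every voxel to the nearest
// background (FALSE) voxel; 0 on background itself.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  // large finite sentinel: infinities poison the parabola intersections
  const double BIG = 1e15;
  for (R_xlen_t i = 0; i < n; i++) out[i] = mask[i] ? BIG : 0.0;
  std::vector<double> line;
  // x pass
  line.resize(nx);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++) {
      R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
      for (int x = 0; x < nx; x++) line[x] = out[base + x];
      dt1d(line, spacing[0]);
      for (int x = 0; x < nx; x++) out[base + x] = line[x];
    }
  // y pass
  line.resize(ny);
  for (int z = 0; z < nz; z++)
    for (int x = 0; x < nx; x++) {
      for (int y = 0; y < ny; y++)
        line[y] = out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
      dt1d(line, spacing[1]);
      for (int y = 0; y < ny; y++)
        out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = line[y];
    }
  // z pass
  line.resize(nz);
  for (int y = 0; y < ny; y++)
    for (int x = 0; x < nx; x++) {
      for (int z = 0; z < nz; z++)
        line[z] = out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
      dt1d(line, spacing[2]);
      for (int z = 0; z < nz; z++)
        out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = line[z];
    }
  return out;
}

// ---------------------------------------------------------------------------
// Neighborhood offset table. conn: 6, 18 or 26.
static void neighbor_offsets(int conn, std::vector<int> &dx,
                             std::vector<int> &dy, std::vector<int> &dz) {
  for (int a = -1; a <= 1; a++)
    for (int b = -1; b <= 1; b++)
      for (int c = -1; c <= 1; c++) {
        if (a == 0 && b == 0 && c == 0) continue;
        int d2 = a * a + b * b + c * c;
        if ((conn == 6 && d2 > 1) || (conn == 18 && d2 > 2)) continue;
        dx.push_back(a);
        dy.push_back(b);
        dz.push_back(c);
      }
}

// Connected components of a 3-D logical array; labels 1..k, background 0.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim, int conn) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> dx, dy, dz;
  neighbor_offsets(conn, dx, dy, dz);
  const int m = (int)dx.size();
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || lab[s] != 0) continue;
    next++;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int x = (int)(cur % nx);
      int y = (int)((cur / nx) % ny);
      int z = (int)(cur / ((R_xlen_t)nx * ny));
      for (int k = 0; k < m; k++) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        R_xlen_t idx = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[idx] && lab[idx] == 0) {
          lab[idx] = next;
          stack.push_back(idx);
        }
      }
    }
  }
  return lab;
}

// 2-D 8- (or 4-) connected labeling of one slice.
// [[Rcpp::export]]
IntegerVector cpp_label2d(LogicalVector mask, IntegerVector dim, int conn) {
  const int nx = dim[0], ny = dim[1];
  const R_xlen_t n = (R_xlen_t)nx * ny;
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || lab[s] != 0) continue;
    next++;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int x = (int)(cur % nx), y = (int)(cur / nx);
      for (int a = -1; a <= 1; a++)
        for (int b = -1; b <= 1; b++) {
          if (a == 0 && b == 0) continue;
          if (conn == 4 && a != 0 && b != 0) continue;
          int xx = x + a, yy = y + b;
          if (xx < 0 || yy < 0 || xx >= nx || yy >= ny) continue;
          R_xlen_t idx = xx + (R_xlen_t)nx * yy;
          if (mask[idx] && lab[idx] == 0) {
            lab[idx] = next;
            stack.push_back(idx);
          }
        }
    }
  }
  return lab;
}

// Threshold-gated region growing: BFS from the seed region, accepting a
// voxel when vol >= its per-voxel threshold. 26-connected.
// [[Rcpp::export]]
LogicalVector cpp_region_grow(NumericVector vol, LogicalVector region,
                              NumericVector thresh, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n);
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < n; i++) {
    out[i] = region[i];
    if (region[i]) stack.push_back(i);
  }
  std::vector<int> dx, dy, dz;
  neighbor_offsets(26, dx, dy, dz);
  while (!stack.empty()) {
    R_xlen_t cur = stack.back();
    stack.pop_back();
    int x = (int)(cur % nx);
    int y = (int)((cur / nx) % ny);
    int z = (int)(cur / ((R_xlen_t)nx * ny));
    for (int k = 0; k < 26; k++) {
      int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
        continue;
      R_xlen_t idx = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
      if (!out[idx] && R_finite(thresh[idx]) && vol[idx] >= thresh[idx]) {
        out[idx] = true;
        stack.push_back(idx);
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// GGMRF / ICM machinery.
//
// Local energy of candidate c at voxel s given the original datum q0 and the
// 26 neighbour values: |q0 - c|^alpha + rho^alpha * lambda^beta *
// sum_r eta_r |c - q_r|^beta, with eta_r = 1/(voxel distance to r).
// The argmin over all Q gray levels provably lies within
// [min(q0, neighbours), max(q0, neighbours)]: outside that interval every
// absolute-difference term strictly decreases as the candidate moves one
// level toward the interval, so the search is restricted there without any
// loss of exactness.

// One in-place raster-order ICM sweep; q is the current estimate, q0 the
// original data. Returns the updated volume (integer gray levels, doubles).
// [[Rcpp::export]]
NumericVector cpp_ggmrf_sweep(NumericVector q, NumericVector q0,
                              IntegerVector dim, double alpha, double beta,
                              double lambda, double rho, int Q,
                              int search_radius) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out = clone(q);
  std::vector<int> dx, dy, dz;
  neighbor_offsets(26, dx, dy, dz);
  std::vector<double> eta(26);
  for (int k = 0; k < 26; k++) {
    double d2 = dx[k] * dx[k] + dy[k] * dy[k] + dz[k] * dz[k];
    eta[k] = 1.0 / std::sqrt(d2);
  }
  const double scale = std::pow(rho, alpha) * std::pow(lambda, beta);
  std::vector<double> ptab(Q), dtab(Q);
  for (int d = 0; d < Q; d++) {
    ptab[d] = scale * std::pow((double)d, beta);
    dtab[d] = std::pow((double)d, alpha);
  }
  double nv[26];
  double ne[26];
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        R_xlen_t s = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        int m = 0;
        int qs = (int)q0[s];
        int lo = qs, hi = qs;
        for (int k = 0; k < 26; k++) {
          int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            continue;
          double v = out[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)];
          nv[m] = v;
          ne[m] = eta[k];
          m++;
          int vi = (int)v;
          if (vi < lo) lo = vi;
          if (vi > hi) hi = vi;
        }
        if (lo < qs - search_radius) lo = qs - search_radius;
        if (hi > qs + search_radius) hi = qs + search_radius;
        double best = INF;
        int bestc = qs;
        for (int c = lo; c <= hi; c++) {
          double e = dtab[std::abs(qs - c)];
          for (int k = 0; k < m; k++)
            e += ne[k] * ptab[(int)std::fabs(c - nv[k])];
          if (e < best) {
            best = e;
            bestc = c;
          }
        }
        out[s] = bestc;
      }
  return out;
}

// Global GGMRF energy: data term plus pairwise term counted once per
// unordered neighbour pair.
// [[Rcpp::export]]
double cpp_ggmrf_energy(NumericVector q, NumericVector q0, IntegerVector dim,
                        double alpha, double beta, double lambda, double rho) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<int> dx, dy, dz;
  neighbor_offsets(26, dx, dy, dz);
  const double scale = std::pow(rho, alpha) * std::pow(lambda, beta);
  double E = 0.0;
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        R_xlen_t s = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        E += std::pow(std::fabs(q0[s] - q[s]), alpha);
        for (int k = 0; k < 26; k++) {
          // count each unordered pair once: positive lexicographic offsets
          if (dz[k] < 0 || (dz[k] == 0 && (dy[k] < 0 || (dy[k] == 0 && dx[k] < 0))))
            continue;
          int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            continue;
          double d2 = dx[k] * dx[k] + dy[k] * dy[k] + dz[k] * dz[k];
          double qr = q[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)];
          E += scale * std::pow(std::fabs(q[s] - qr), beta) / std::sqrt(d2);
        }
      }
  return E;
}

// ---------------------------------------------------------------------------
// Separable Gaussian blur, sigma in voxels per axis; truncated at 3 sigma
// with boundary renormalisation.
static void blur_axis(std::vector<double> &src, std::vector<double> &dst,
                      int nx, int ny, int nz, int axis, double sigma) {
  if (sigma <= 0) {
    dst = src;
    return;
  }
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  for (int i = -r; i <= r; i++) k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
  int dims[3] = {nx, ny, nz};
  R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  int n = dims[axis];
  R_xlen_t st = stride[axis];
  for (int z = 0; z < (axis == 2 ? 1 : nz); z++)
    for (int y = 0; y < (axis == 1 ? 1 : ny); y++)
      for (int x = 0; x < (axis == 0 ? 1 : nx); x++) {
        R_xlen_t base = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        for (int i = 0; i < n; i++) {
          double acc = 0, wsum = 0;
          int j0 = std::max(0, i - r), j1 = std::min(n - 1, i + r);
          for (int j = j0; j <= j1; j++) {
            double w = k[j - i + r];
            acc += w * src[base + (R_xlen_t)j * st];
            wsum += w;
          }
          dst[base + (R_xlen_t)i * st] = acc / wsum;
        }
      }
}

// [[Rcpp::export]]
NumericVector cpp_gauss_blur3d(NumericVector vol, IntegerVector dim,
                               NumericVector sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(n), b(n);
  for (R_xlen_t i = 0; i < n; i++) a[i] = vol[i];
  blur_axis(a, b, nx, ny, nz, 0, sigma[0]);
  blur_axis(b, a, nx, ny, nz, 1, sigma[1]);
  blur_axis(a, b, nx, ny, nz, 2, sigma[2]);
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = b[i];
  return out;
}

// ---------------------------------------------------------------------------
// Iso-surface extraction by marching over the Kuhn 6-tetrahedra cube
// decomposition. Every tetrahedron contains the cube's main diagonal, and
// the induced face diagonals agree between adjacent cubes, so the extracted
// mesh is watertight. Vertices lie on lattice edges and are welded through
// a (node_lo, node_hi) hash. Triangles are oriented with normals pointing
// from the above-iso (inside) region outward.

struct MeshAcc {
  std::vector<double> vx, vy, vz;
  std::vector<int> f; // triangle vertex indices, 0-based, groups of 3
  std::unordered_map<uint64_t, int> edge_map;
};

static int edge_vertex(MeshAcc &M, R_xlen_t n1, R_xlen_t n2, double v1,
                       double v2, const double *p1, const double *p2,
                       double iso) {
  uint64_t a = (uint64_t)std::min(n1, n2), b = (uint64_t)std::max(n1, n2);
  uint64_t key = (a << 32) | b;
  // key collision impossible for grids < 2^32 nodes; enforce order by value
  auto it = M.edge_map.find(key);
  if (it != M.edge_map.end()) return it->second;
  double t = (iso - v1) / (v2 - v1);
  if (t < 0) t = 0;
  if (t > 1) t = 1;
  int id = (int)M.vx.size();
  M.vx.push_back(p1[0] + t * (p2[0] - p1[0]));
  M.vy.push_back(p1[1] + t * (p2[1] - p1[1]));
  M.vz.push_back(p1[2] + t * (p2[2] - p1[2]));
  M.edge_map[key] = id;
  return id;
}

static void add_tri(MeshAcc &M, int a, int b, int c, const double *outward) {
  // orient so the normal has positive dot with the inside->outside direction
  double ux = M.vx[b] - M.vx[a], uy = M.vy[b] - M.vy[a], uz = M.vz[b] - M.vz[a];
  double wx = M.vx[c] - M.vx[a], wy = M.vy[c] - M.vy[a], wz = M.vz[c] - M.vz[a];
  double nxv = uy * wz - uz * wy, nyv = uz * wx - ux * wz, nzv = ux * wy - uy * wx;
  double d = nxv * outward[0] + nyv * outward[1] + nzv * outward[2];
  if (d < 0) std::swap(b, c);
  M.f.push_back(a);
  M.f.push_back(b);
  M.f.push_back(c);
}

// [[Rcpp::export]]
List cpp_march_tets(NumericVector field, IntegerVector dim, double iso,
                    NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  // Kuhn decomposition: node paths 0 -> e_{p1} -> e_{p1}+e_{p2} -> (1,1,1)
  static const int tets[6][4][3] = {
      {{0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {1, 1, 1}},
      {{0, 0, 0}, {1, 0, 0}, {1, 0, 1}, {1, 1, 1}},
      {{0, 0, 0}, {0, 1, 0}, {1, 1, 0}, {1, 1, 1}},
      {{0, 0, 0}, {0, 1, 0}, {0, 1, 1}, {1, 1, 1}},
      {{0, 0, 0}, {0, 0, 1}, {1, 0, 1}, {1, 1, 1}},
      {{0, 0, 0}, {0, 0, 1}, {0, 1, 1}, {1, 1, 1}}};
  MeshAcc M;
  double P[4][3];
  double V[4];
  R_xlen_t N[4];
  for (int z = 0; z < nz - 1; z++)
    for (int y = 0; y < ny - 1; y++)
      for (int x = 0; x < nx - 1; x++) {
        for (int t = 0; t < 6; t++) {
          int nin = 0;
          int in_idx[4], out_idx[4];
          int nout = 0;
          for (int v = 0; v < 4; v++) {
            int xx = x + tets[t][v][0], yy = y + tets[t][v][1],
                zz = z + tets[t][v][2];
            N[v] = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
            V[v] = field[N[v]];
            P[v][0] = xx * spacing[0];
            P[v][1] = yy * spacing[1];
            P[v][2] = zz * spacing[2];
            if (V[v] > iso)
              in_idx[nin++] = v;
            else
              out_idx[nout++] = v;
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1 || nin == 3) {
            int a = (nin == 1) ? in_idx[0] : out_idx[0];
            int o[3];
            int c = 0;
            for (int v = 0; v < 4; v++)
              if (v != a) o[c++] = v;
            int e0 = edge_vertex(M, N[a], N[o[0]], V[a], V[o[0]], P[a], P[o[0]], iso);
            int e1 = edge_vertex(M, N[a], N[o[1]], V[a], V[o[1]], P[a], P[o[1]], iso);
            int e2 = edge_vertex(M, N[a], N[o[2]], V[a], V[o[2]], P[a], P[o[2]], iso);
            double dir[3];
            if (nin == 1) { // a inside, others outside: outward = others - a
              for (int d = 0; d < 3; d++)
                dir[d] = (P[o[0]][d] + P[o[1]][d] + P[o[2]][d]) / 3.0 - P[a][d];
            } else { // a outside, others inside: outward = a - others
              for (int d = 0; d < 3; d++)
                dir[d] = P[a][d] - (P[o[0]][d] + P[o[1]][d] + P[o[2]][d]) / 3.0;
            }
            add_tri(M, e0, e1, e2, dir);
          } else { // 2 in, 2 out
            int a = in_idx[0], b = in_idx[1], c = out_idx[0], d = out_idx[1];
            int eac = edge_vertex(M, N[a], N[c], V[a], V[c], P[a], P[c], iso);
            int ead = edge_vertex(M, N[a], N[d], V[a], V[d], P[a], P[d], iso);
            int ebc = edge_vertex(M, N[b], N[c], V[b], V[c], P[b], P[c], iso);
            int ebd = edge_vertex(M, N[b], N[d], V[b], V[d], P[b], P[d], iso);
            double dir[3];
            for (int k = 0; k < 3; k++)
              dir[k] = (P[c][k] + P[d][k]) / 2.0 - (P[a][k] + P[b][k]) / 2.0;
            // quad cycle eac -> ead -> ebd -> ebc
            add_tri(M, eac, ead, ebd, dir);
            add_tri(M, eac, ebd, ebc, dir);
          }
        }
      }
  int nv = (int)M.vx.size();
  NumericMatrix verts(nv, 3);
  for (int i = 0; i < nv; i++) {
    verts(i, 0) = M.vx[i];
    verts(i, 1) = M.vy[i];
    verts(i, 2) = M.vz[i];
  }
  int nf = (int)M.f.size() / 3;
  IntegerMatrix faces(nf, 3);
  for (int i = 0; i < nf; i++) {
    faces(i, 0) = M.f[3 * i] + 1;
    faces(i, 1) = M.f[3 * i + 1] + 1;
    faces(i, 2) = M.f[3 * i + 2] + 1;
  }
  return List::create(_["vertices"] = verts, _["faces"] = faces);
}

// ---------------------------------------------------------------------------
// Per-vertex principal curvatures by least-squares fit of the second
// fundamental form to finite-difference normal-curvature samples
// (Chen-Schmitt style). Inputs: vertices (n x 3, mm), unit normals (n x 3),
// neighbour adjacency in CSR form (nbr_idx 1-based, nbr_ptr length n+1).
// Returns k1 >= k2 per vertex plus the count of usable samples.
// [[Rcpp::export]]
List cpp_vertex_curvatures(NumericMatrix verts, NumericMatrix normals,
                           IntegerVector nbr_idx, IntegerVector nbr_ptr) {
  const int n = verts.nrow();
  NumericVector k1(n), k2(n), e1x(n), e1y(n), e1z(n);
  IntegerVector nsamp(n);
  for (int i = 0; i < n; i++) {
    double ni[3] = {normals(i, 0), normals(i, 1), normals(i, 2)};
    // orthonormal tangent basis (u, w)
    double ax = std::fabs(ni[0]) < 0.9 ? 1.0 : 0.0;
    double ay = ax == 1.0 ? 0.0 : 1.0;
    double u[3] = {ay * ni[2] - 0.0 * ni[1], 0.0 * ni[0] - ax * ni[2],
                   ax * ni[1] - ay * ni[0]};
    double un = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
    for (int d = 0; d < 3; d++) u[d] /= un;
    double w[3] = {ni[1] * u[2] - ni[2] * u[1], ni[2] * u[0] - ni[0] * u[2],
                   ni[0] * u[1] - ni[1] * u[0]};
    // normal equations for k(t) = A tx^2 + 2 B tx ty + C ty^2
    double S[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
    double b[3] = {0, 0, 0};
    int m = 0;
    for (int p = nbr_ptr[i]; p < nbr_ptr[i + 1]; p++) {
      int j = nbr_idx[p] - 1;
      double e[3] = {verts(j, 0) - verts(i, 0), verts(j, 1) - verts(i, 1),
                     verts(j, 2) - verts(i, 2)};
      double elen2 = e[0] * e[0] + e[1] * e[1] + e[2] * e[2];
      if (elen2 <= 0) continue;
      double edn = e[0] * ni[0] + e[1] * ni[1] + e[2] * ni[2];
      double tp[3] = {e[0] - edn * ni[0], e[1] - edn * ni[1], e[2] - edn * ni[2]};
      double tl = std::sqrt(tp[0] * tp[0] + tp[1] * tp[1] + tp[2] * tp[2]);
      if (tl < 1e-9 * std::sqrt(elen2)) continue; // e parallel to normal
      double tx = (tp[0] * u[0] + tp[1] * u[1] + tp[2] * u[2]) / tl;
      double ty = (tp[0] * w[0] + tp[1] * w[1] + tp[2] * w[2]) / tl;
      double dn[3] = {normals(j, 0) - ni[0], normals(j, 1) - ni[1],
                      normals(j, 2) - ni[2]};
      double kij = (e[0] * dn[0] + e[1] * dn[1] + e[2] * dn[2]) / elen2;
      double X[3] = {tx * tx, 2.0 * tx * ty, ty * ty};
      for (int r = 0; r < 3; r++) {
        b[r] += X[r] * kij;
        for (int c = 0; c < 3; c++) S[r][c] += X[r] * X[c];
      }
      m++;
    }
    nsamp[i] = m;
    if (m < 3) {
      k1[i] = NA_REAL;
      k2[i] = NA_REAL;
      continue;
    }
    // solve 3x3 by Cramer with ridge fallback
    double A[3][3];
    for (int r = 0; r < 3; r++)
      for (int c = 0; c < 3; c++) A[r][c] = S[r][c];
    double det = A[0][0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1]) -
                 A[0][1] * (A[1][0] * A[2][2] - A[1][2] * A[2][0]) +
                 A[0][2] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]);
    if (std::fabs(det) < 1e-12) {
      for (int r = 0; r < 3; r++) A[r][r] += 1e-8;
      det = A[0][0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1]) -
            A[0][1] * (A[1][0] * A[2][2] - A[1][2] * A[2][0]) +
            A[0][2] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]);
    }
    double sol[3];
    for (int c = 0; c < 3; c++) {
      double T[3][3];
      for (int r = 0; r < 3; r++)
        for (int cc = 0; cc < 3; cc++) T[r][cc] = A[r][cc];
      for (int r = 0; r < 3; r++) T[r][c] = b[r];
      double dc = T[0][0] * (T[1][1] * T[2][2] - T[1][2] * T[2][1]) -
                  T[0][1] * (T[1][0] * T[2][2] - T[1][2] * T[2][0]) +
                  T[0][2] * (T[1][0] * T[2][1] - T[1][1] * T[2][0]);
      sol[c] = dc / det;
    }
    // eigen-decompose [[A,B],[B,C]]
    double Aq = sol[0], Bq = sol[1], Cq = sol[2];
    double tr = Aq + Cq, dd = std::sqrt(std::max(0.0, (Aq - Cq) * (Aq - Cq) / 4 + Bq * Bq));
    double l1 = tr / 2 + dd, l2 = tr / 2 - dd;
    k1[i] = l1;
    k2[i] = l2;
    // principal direction for l1 in tangent coords -> 3-D
    double vx0, vy0;
    if (std::fabs(Bq) > 1e-14) {
      vx0 = l1 - Cq;
      vy0 = Bq;
    } else if (Aq >= Cq) {
      vx0 = 1;
      vy0 = 0;
    } else {
      vx0 = 0;
      vy0 = 1;
    }
    double vn = std::sqrt(vx0 * vx0 + vy0 * vy0);
    if (vn > 0) {
      vx0 /= vn;
      vy0 /= vn;
    }
    e1x[i] = vx0 * u[0] + vy0 * w[0];
    e1y[i] = vx0 * u[1] + vy0 * w[1];
    e1z[i] = vx0 * u[2] + vy0 * w[2];
  }
  return List::create(_["k1"] = k1, _["k2"] = k2, _["n_samples"] = nsamp,
                      _["E1"] = cbind(NumericVector(e1x), NumericVector(e1y),
                                      NumericVector(e1z)));
}
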