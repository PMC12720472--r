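#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Volumes are R arrays with dim = (nz, ny, nx); linear index = z + nz*(y + ny*x).
// Out-of-bounds voxels are background throughout.

static inline int cube_idx(int dz, int dy, int dx) {
  return (dz + 1) + 3 * ((dy + 1) + 3 * (dx + 1));
}

// 26-adjacency between cells of the 3x3x3 cube, and the 6-adjacency used for
// the background condition of the simple-point test (restricted to the
// 18-neighbourhood of the centre).
struct CubeTables {
  std::vector< std::vector<int> > adj26;   // over all 27 cells
  std::vector< std::vector<int> > adj6;    // over all 27 cells, face moves only
  std::vector<int> n18;                    // indices of the 18-neighbourhood
  std::vector<bool> is_n18;
  std::vector<int> face;                   // the 6 face neighbours of centre
  CubeTables() : adj26(27), adj6(27), is_n18(27, false) {
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          int i = cube_idx(dz, dy, dx);
          int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
          if (man >= 1 && man <= 2) { n18.push_back(i); is_n18[i] = true; }
          if (man == 1) face.push_back(i);
          for (int ex = -1; ex <= 1; ++ex)
            for (int ey = -1; ey <= 1; ++ey)
              for (int ez = -1; ez <= 1; ++ez) {
                int j = cube_idx(ez, ey, ex);
                if (i == j) continue;
                int adx = std::abs(dx - ex), ady = std::abs(dy - ey),
                    adz = std::abs(dz - ez);
                if (adx <= 1 && ady <= 1 && adz <= 1) {
                  adj26[i].push_back(j);
                  if (adx + ady + adz == 1) adj6[i].push_back(j);
                }
              }
        }
  }
};

static CubeTables TAB;

// Extract the 3x3x3 neighbourhood of voxel (z,y,x) into cube[27].
static inline void extract_cube(const int* vol, int nz, int ny, int nx,
                                int z, int y, int x, bool* cube) {
  for (int dx = -1; dx <= 1; ++dx) {
    int xx = x + dx;
    for (int dy = -1; dy <= 1; ++dy) {
      int yy = y + dy;
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz;
        bool v = false;
        if (zz >= 0 && zz < nz && yy >= 0 && yy < ny && xx >= 0 && xx < nx)
          v = vol[zz + (size_t)nz * (yy + (size_t)ny * xx)] != 0;
        cube[cube_idx(dz, dy, dx)] = v;
      }
    }
  }
}

static inline int count_object_neighbors(const bool* cube) {
  int n = 0;
  for (int i = 0; i < 27; ++i) if (i != cube_idx(0, 0, 0) && cube[i]) ++n;
  return n;
}

// Simple-point test (Bertrand & Malandain characterisation for 26/6
// connectivity): the object restricted to N26* must form one 26-component,
// and the background restricted to N18 must form one 6-component touching a
// face neighbour.
static bool is_simple(const bool* cube) {
  const int centre = cube_idx(0, 0, 0);
  // object components in N26*
  bool seen[27] = {false};
  int ncomp = 0;
  for (int i = 0; i < 27; ++i) {
    if (i == centre || !cube[i] || seen[i]) continue;
    if (++ncomp > 1) return false;
    std::vector<int> stack(1, i);
    seen[i] = true;
    while (!stack.empty()) {
      int c = stack.back(); stack.pop_back();
      for (int j : TAB.adj26[c])
        if (j != centre && cube[j] && !seen[j]) { seen[j] = true; stack.push_back(j); }
    }
  }
  if (ncomp != 1) return false;
  // background 6-components in N18, seeded from face neighbours
  bool bseen[27] = {false};
  int nbcomp = 0;
  for (int f : TAB.face) {
    if (cube[f] || bseen[f]) continue;
    if (++nbcomp > 1) return false;
    std::vector<int> stack(1, f);
    bseen[f] = true;
    while (!stack.empty()) {
      int c = stack.back(); stack.pop_back();
      for (int j : TAB.adj6[c])
        if (TAB.is_n18[j] && !cube[j] && !bseen[j]) { bseen[j] = true; stack.push_back(j); }
    }
  }
  return nbcomp == 1;
}

// [[Rcpp::export]]
IntegerVector thin3d_cpp(IntegerVector vol, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  IntegerVector out = clone(vol);
  int* v = INTEGER(out);
  // six border directions: U, D, N, S, W, E as (dz, dy, dx)
  const int dir[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  bool cube[27];
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      std::vector<size_t> cand;
      for (int x = 0; x < nx; ++x)
        for (int y = 0; y < ny; ++y)
          for (int z = 0; z < nz; ++z) {
            size_t i = z + (size_t)nz * (y + (size_t)ny * x);
            if (!v[i]) continue;
            int zz = z + dir[d][0], yy = y + dir[d][1], xx = x + dir[d][2];
            bool bg = true;
            if (zz >= 0 && zz < nz && yy >= 0 && yy < ny && xx >= 0 && xx < nx)
              bg = v[zz + (size_t)nz * (yy + (size_t)ny * xx)] == 0;
            if (!bg) continue;
            extract_cube(v, nz, ny, nx, z, y, x, cube);
            int nn = count_object_neighbors(cube);
            if (nn <= 1) continue;              // endpoints (and isolated) kept
            if (is_simple(cube)) cand.push_back(i);
          }
      // sequential recheck keeps deletions topology-preserving
      for (size_t i : cand) {
        int x = (int)(i / ((size_t)nz * ny));
        int rem = (int)(i % ((size_t)nz * ny));
        int y = rem / nz, z = rem % nz;
        extract_cube(v, nz, ny, nx, z, y, x, cube);
        if (count_object_neighbors(cube) <= 1) continue;
        if (is_simple(cube)) { v[i] = 0; changed = true; }
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export]]
IntegerVector label_components_cpp(IntegerVector vol, IntegerVector dims,
                                   int connectivity) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  size_t n = (size_t)nz * ny * nx;
  const int* v = INTEGER(vol);
  IntegerVector lab(n, 0);
  int* L = INTEGER(lab);
  std::vector<std::array<int,3> > offs;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (man == 0) continue;
        if (connectivity == 6 && man != 1) continue;
        offs.push_back({dz, dy, dx});
      }
  int next = 0;
  std::vector<size_t> stack;
  for (size_t i = 0; i < n; ++i) {
    if (!v[i] || L[i]) continue;
    L[i] = ++next;
    stack.assign(1, i);
    while (!stack.empty()) {
      size_t c = stack.back(); stack.pop_back();
      int x = (int)(c / ((size_t)nz * ny));
      int rem = (int)(c % ((size_t)nz * ny));
      int y = rem / nz, z = rem % nz;
      for (auto& o : offs) {
        int zz = z + o[0], yy = y + o[1], xx = x + o[2];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        size_t j = zz + (size_t)nz * (yy + (size_t)ny * xx);
        if (v[j] && !L[j]) { L[j] = next; stack.push_back(j); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// [[Rcpp::export]]
IntegerVector neighbor_count_cpp(IntegerVector vol, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  size_t n = (size_t)nz * ny * nx;
  const int* v = INTEGER(vol);
  IntegerVector cnt(n, 0);
  int* C = INTEGER(cnt);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        size_t i = z + (size_t)nz * (y + (size_t)ny * x);
        if (!v[i]) continue;
        int c = 0;
        for (int dx = -1; dx <= 1; ++dx)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dz = -1; dz <= 1; ++dz) {
              if (!dx && !dy && !dz) continue;
              int zz = z + dz, yy = y + dy, xx = x + dx;
              if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
                continue;
              if (v[zz + (size_t)nz * (yy + (size_t)ny * xx)]) ++c;
            }
        C[i] = c;
      }
  cnt.attr("dim") = dims;
  return cnt;
}

// Eigenvalues of symmetric 3x3 matrices, returned sorted by increasing
// absolute value (analytic trigonometric method).
// [[Rcpp::export]]
NumericMatrix sym3_eigenvalues_cpp(NumericVector a11, NumericVector a22,
                                   NumericVector a33, NumericVector a12,
                                   NumericVector a13, NumericVector a23) {
  R_xlen_t n = a11.size();
  NumericMatrix out(n, 3);
  for (R_xlen_t i = 0; i < n; ++i) {
    double A11 = a11[i], A22 = a22[i], A33 = a33[i];
    double A12 = a12[i], A13 = a13[i], A23 = a23[i];
    double e[3];
    double p1 = A12 * A12 + A13 * A13 + A23 * A23;
    if (p1 == 0.0) {
      e[0] = A11; e[1] = A22; e[2] = A33;
    } else {
      double q = (A11 + A22 + A33) / 3.0;
      double p2 = (A11 - q) * (A11 - q) + (A22 - q) * (A22 - q) +
                  (A33 - q) * (A33 - q) + 2.0 * p1;
      double p = std::sqrt(p2 / 6.0);
      double b11 = (A11 - q) / p, b22 = (A22 - q) / p, b33 = (A33 - q) / p;
      double b12 = A12 / p, b13 = A13 / p, b23 = A23 / p;
      double detB = b11 * (b22 * b33 - b23 * b23) -
                    b12 * (b12 * b33 - b23 * b13) +
                    b13 * (b12 * b23 - b22 * b13);
      double r = detB / 2.0;
      if (r < -1.0) r = -1.0;
      if (r > 1.0) r = 1.0;
      double phi = std::acos(r) / 3.0;
      e[0] = q + 2.0 * p * std::cos(phi);
      e[2] = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
      e[1] = 3.0 * q - e[0] - e[2];
    }
    // sort by |lambda|
    for (int a = 0; a < 2; ++a)
      for (int b = 0; b < 2 - a; ++b)
        if (std::fabs(e[b]) > std::fabs(e[b + 1])) std::swap(e[b], e[b + 1]);
    out(i, 0) = e[0]; out(i, 1) = e[1]; out(i, 2) = e[2];
  }
  return out;
}
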