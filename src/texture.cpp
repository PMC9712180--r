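// Voxel-level kernels for gray-level texture matrices on 3D discretized ROIs.
// Level grids are integer arrays with 0 marking voxels outside the ROI;
// voxels beyond the grid are treated as outside the ROI throughout.
#include <Rcpp.h>
#include <vector>
#include <cstdlib>
using namespace Rcpp;

// 13 unique 3D directions at Chebyshev distance 1 (26-connectivity up to sign)
static const int DIR13[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1}, {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

static void get_dims(const IntegerVector &a, int &nx, int &ny, int &nz) {
  IntegerVector d = a.attr("dim");
  if (d.size() != 3) stop("expected a 3D array");
  nx = d[0]; ny = d[1]; nz = d[2];
}

// [[Rcpp::export(name = ".cppDirections13")]]
IntegerMatrix cpp_directions13() {
  IntegerMatrix m(13, 3);
  for (int i = 0; i < 13; ++i)
    for (int j = 0; j < 3; ++j) m(i, j) = DIR13[i][j];
  return m;
}

// Symmetric co-occurrence counts per direction: ng x ng x 13.
// [[Rcpp::export(name = ".cppGlcmStack")]]
NumericVector cpp_glcm_stack(IntegerVector levels, int ng, int dist) {
  int nx, ny, nz; get_dims(levels, nx, ny, nz);
  NumericVector out(static_cast<R_xlen_t>(ng) * ng * 13);
  out.attr("dim") = IntegerVector::create(ng, ng, 13);
  for (int d = 0; d < 13; ++d) {
    int dx = DIR13[d][0] * dist, dy = DIR13[d][1] * dist, dz = DIR13[d][2] * dist;
    double *slab = &out[static_cast<R_xlen_t>(d) * ng * ng];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int li = levels[idx3(x, y, z, nx, ny)];
          if (li == 0) continue;
          int x2 = x + dx, y2 = y + dy, z2 = z + dz;
          if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz) continue;
          int lj = levels[idx3(x2, y2, z2, nx, ny)];
          if (lj == 0) continue;
          slab[(li - 1) + ng * (lj - 1)] += 1.0;  // both orders accumulated
          slab[(lj - 1) + ng * (li - 1)] += 1.0;  // by symmetry
        }
  }
  return out;
}

// Run-length counts per direction: ng x maxlen x 13.
// [[Rcpp::export(name = ".cppGlrlmStack")]]
NumericVector cpp_glrlm_stack(IntegerVector levels, int ng) {
  int nx, ny, nz; get_dims(levels, nx, ny, nz);
  int maxlen = std::max(nx, std::max(ny, nz));
  NumericVector out(static_cast<R_xlen_t>(ng) * maxlen * 13);
  out.attr("dim") = IntegerVector::create(ng, maxlen, 13);
  for (int d = 0; d < 13; ++d) {
    int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    double *slab = &out[static_cast<R_xlen_t>(d) * ng * maxlen];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int li = levels[idx3(x, y, z, nx, ny)];
          if (li == 0) continue;
          // run start: predecessor outside grid/ROI or different level
          int xp = x - dx, yp = y - dy, zp = z - dz;
          bool start = true;
          if (xp >= 0 && xp < nx && yp >= 0 && yp < ny && zp >= 0 && zp < nz)
            start = levels[idx3(xp, yp, zp, nx, ny)] != li;
          if (!start) continue;
          int len = 1, x2 = x + dx, y2 = y + dy, z2 = z + dz;
          while (x2 >= 0 && x2 < nx && y2 >= 0 && y2 < ny && z2 >= 0 && z2 < nz &&
                 levels[idx3(x2, y2, z2, nx, ny)] == li) {
            ++len; x2 += dx; y2 += dy; z2 += dz;
          }
          slab[(li - 1) + ng * (len - 1)] += 1.0;
        }
  }
  return out;
}

// Chebyshev distance of each in-mask voxel to the nearest voxel outside the
// mask (out-of-grid counts as outside): two-pass chamfer over the full
// 26-neighborhood, exact for the Chebyshev metric. Outside voxels get 0.
// [[Rcpp::export(name = ".cppChebyshevDistance")]]
IntegerVector cpp_chebyshev_distance(LogicalVector mask) {
  int nx, ny, nz;
  {
    IntegerVector d = mask.attr("dim");
    if (d.size() != 3) stop("expected a 3D array");
    nx = d[0]; ny = d[1]; nz = d[2];
  }
  int n = nx * ny * nz;
  const int BIG = nx + ny + nz + 3;
  std::vector<int> dist(n);
  for (int i = 0; i < n; ++i) dist[i] = mask[i] ? BIG : 0;
  // forward pass
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = idx3(x, y, z, nx, ny);
        if (dist[i] == 0) continue;
        int best = dist[i];
        for (int dz = -1; dz <= 0; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dz == 0 && (dy > 0 || (dy == 0 && dx >= 0))) continue;  // causal half
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              int dn = (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
                       ? 0 : dist[idx3(x2, y2, z2, nx, ny)];
              if (dn + 1 < best) best = dn + 1;
            }
        dist[i] = best;
      }
  // backward pass
  for (int z = nz - 1; z >= 0; --z)
    for (int y = ny - 1; y >= 0; --y)
      for (int x = nx - 1; x >= 0; --x) {
        int i = idx3(x, y, z, nx, ny);
        if (dist[i] == 0) continue;
        int best = dist[i];
        for (int dz = 0; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dz == 0 && (dy < 0 || (dy == 0 && dx <= 0))) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              int dn = (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
                       ? 0 : dist[idx3(x2, y2, z2, nx, ny)];
              if (dn + 1 < best) best = dn + 1;
            }
        dist[i] = best;
      }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = dist[i];
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return out;
}

// 26-connected zones of equal gray level; returns per-zone level, size and
// minimum Chebyshev border distance (for GLSZM/GLDZM).
// [[Rcpp::export(name = ".cppZones")]]
DataFrame cpp_zones(IntegerVector levels) {
  int nx, ny, nz; get_dims(levels, nx, ny, nz);
  int n = nx * ny * nz;
  LogicalVector roi(n);
  for (int i = 0; i < n; ++i) roi[i] = levels[i] > 0;
  roi.attr("dim") = levels.attr("dim");
  IntegerVector dmap = cpp_chebyshev_distance(roi);
  std::vector<int> label(n, 0);
  std::vector<int> zlevel, zsize, zdist;
  std::vector<int> stack;
  int nzone = 0;
  for (int seed = 0; seed < n; ++seed) {
    if (levels[seed] == 0 || label[seed] != 0) continue;
    ++nzone;
    int lev = levels[seed], size = 0, mind = dmap[seed];
    stack.clear(); stack.push_back(seed); label[seed] = nzone;
    while (!stack.empty()) {
      int i = stack.back(); stack.pop_back();
      ++size;
      if (dmap[i] < mind) mind = dmap[i];
      int z = i / (nx * ny), r = i % (nx * ny), y = r / nx, x = r % nx;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int x2 = x + dx, y2 = y + dy, z2 = z + dz;
            if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz) continue;
            int j = idx3(x2, y2, z2, nx, ny);
            if (label[j] == 0 && levels[j] == lev) {
              label[j] = nzone;
              stack.push_back(j);
            }
          }
    }
    zlevel.push_back(lev); zsize.push_back(size); zdist.push_back(mind);
  }
  return DataFrame::create(_["level"] = wrap(zlevel),
                           _["size"] = wrap(zsize),
                           _["distance"] = wrap(zdist));
}

// Dependence counts: rows = gray level, columns = dependence k = 0..26
// (number of in-ROI 26-neighbors with |level difference| <= alpha).
// [[Rcpp::export(name = ".cppNgldm")]]
NumericMatrix cpp_ngldm(IntegerVector levels, int ng, int alpha) {
  int nx, ny, nz; get_dims(levels, nx, ny, nz);
  NumericMatrix out(ng, 27);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int li = levels[idx3(x, y, z, nx, ny)];
        if (li == 0) continue;
        int k = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz) continue;
              int lj = levels[idx3(x2, y2, z2, nx, ny)];
              if (lj != 0 && std::abs(lj - li) <= alpha) ++k;
            }
        out(li - 1, k) += 1.0;
      }
  return out;
}

// Neighborhood gray tone difference accumulators: per level the count n_i of
// ROI voxels with at least one ROI neighbor and the summed absolute
// difference s_i between the voxel level and its mean ROI-neighbor level.
// [[Rcpp::export(name = ".cppNgtdm")]]
List cpp_ngtdm(IntegerVector levels, int ng) {
  int nx, ny, nz; get_dims(levels, nx, ny, nz);
  NumericVector ni(ng), si(ng);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int li = levels[idx3(x, y, z, nx, ny)];
        if (li == 0) continue;
        double sum = 0.0; int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz) continue;
              int lj = levels[idx3(x2, y2, z2, nx, ny)];
              if (lj != 0) { sum += lj; ++cnt; }
            }
        if (cnt == 0) continue;
        ni[li - 1] += 1.0;
        si[li - 1] += std::abs(li - sum / cnt);
      }
  return List::create(_["n"] = ni, _["s"] = si);
}
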