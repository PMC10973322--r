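#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Gray-level matrix accumulation kernels.
//
// All kernels take a discretised level array: an integer vector with a
// (nx, ny, nz) dim attribute where in-ROI voxels hold levels 1..ng and
// voxels outside the ROI hold 0.  Offsets/directions are integer matrices
// with one (dx, dy, dz) row per neighbour.

static inline R_xlen_t idx3(int x, int y, int z, int nx, int ny) {
  return (R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)z);
}

// copy an offsets matrix into contiguous arrays for fast inner loops
static void copyOffsets(const IntegerMatrix &offsets, std::vector<int> &ox,
                        std::vector<int> &oy, std::vector<int> &oz) {
  const int nd = offsets.nrow();
  ox.resize(nd); oy.resize(nd); oz.resize(nd);
  for (int d = 0; d < nd; ++d) {
    ox[d] = offsets(d, 0); oy[d] = offsets(d, 1); oz[d] = offsets(d, 2);
  }
}

// [[Rcpp::export(name = ".cpp_glcm_counts")]]
NumericVector cpp_glcm_counts(IntegerVector levels, IntegerVector dim,
                              IntegerMatrix offsets, int ng) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nd = offsets.nrow();
  NumericVector counts((R_xlen_t)ng * ng * nd);
  counts.attr("dim") = IntegerVector::create(ng, ng, nd);
  for (int d = 0; d < nd; ++d) {
    const int dx = offsets(d, 0), dy = offsets(d, 1), dz = offsets(d, 2);
    const R_xlen_t base = (R_xlen_t)d * ng * ng;
    for (int z = 0; z < nz; ++z) {
      const int z2 = z + dz;
      if (z2 < 0 || z2 >= nz) continue;
      for (int y = 0; y < ny; ++y) {
        const int y2 = y + dy;
        if (y2 < 0 || y2 >= ny) continue;
        for (int x = 0; x < nx; ++x) {
          const int x2 = x + dx;
          if (x2 < 0 || x2 >= nx) continue;
          const int gi = levels[idx3(x, y, z, nx, ny)];
          if (gi == 0) continue;
          const int gj = levels[idx3(x2, y2, z2, nx, ny)];
          if (gj == 0) continue;
          // symmetric matrix: count the pair in both orders
          counts[base + (gi - 1) + (R_xlen_t)ng * (gj - 1)] += 1.0;
          counts[base + (gj - 1) + (R_xlen_t)ng * (gi - 1)] += 1.0;
        }
      }
    }
  }
  return counts;
}

// Dependence counts: for every in-ROI voxel, the number of in-ROI
// neighbours whose level differs by at most alpha.  Returns an
// ng x (n_offsets + 1) count matrix; column k holds dependence k-1.
// [[Rcpp::export(name = ".cpp_gldm_counts")]]
NumericMatrix cpp_gldm_counts(IntegerVector levels, IntegerVector dim,
                              IntegerMatrix offsets, int ng, int alpha) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nd = offsets.nrow();
  std::vector<int> ox, oy, oz;
  copyOffsets(offsets, ox, oy, oz);
  NumericMatrix counts(ng, nd + 1);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int gi = levels[idx3(x, y, z, nx, ny)];
        if (gi == 0) continue;
        int dep = 0;
        for (int d = 0; d < nd; ++d) {
          const int x2 = x + ox[d], y2 = y + oy[d], z2 = z + oz[d];
          if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
            continue;
          const int gj = levels[idx3(x2, y2, z2, nx, ny)];
          if (gj == 0) continue;
          if (std::abs(gi - gj) <= alpha) ++dep;
        }
        counts(gi - 1, dep) += 1.0;
      }
  return counts;
}

// Run-length counts along each direction.  A run is a maximal sequence of
// in-ROI voxels with equal level; out-of-ROI voxels and volume borders
// break runs.  Returns ng x maxlen x ndir counts.
// [[Rcpp::export(name = ".cpp_glrlm_counts")]]
NumericVector cpp_glrlm_counts(IntegerVector levels, IntegerVector dim,
                               IntegerMatrix dirs, int ng) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nd = dirs.nrow();
  const int maxlen = std::max(std::max(nx, ny), nz);
  NumericVector counts((R_xlen_t)ng * maxlen * nd);
  counts.attr("dim") = IntegerVector::create(ng, maxlen, nd);
  for (int d = 0; d < nd; ++d) {
    const int dx = dirs(d, 0), dy = dirs(d, 1), dz = dirs(d, 2);
    const R_xlen_t base = (R_xlen_t)d * ng * maxlen;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          const int gi = levels[idx3(x, y, z, nx, ny)];
          if (gi == 0) continue;
          // run start: predecessor out of bounds, out of ROI or different
          const int xp = x - dx, yp = y - dy, zp = z - dz;
          if (xp >= 0 && xp < nx && yp >= 0 && yp < ny && zp >= 0 && zp < nz &&
              levels[idx3(xp, yp, zp, nx, ny)] == gi)
            continue;
          int len = 1;
          int xc = x + dx, yc = y + dy, zc = z + dz;
          while (xc >= 0 && xc < nx && yc >= 0 && yc < ny && zc >= 0 &&
                 zc < nz && levels[idx3(xc, yc, zc, nx, ny)] == gi) {
            ++len;
            xc += dx; yc += dy; zc += dz;
          }
          counts[base + (gi - 1) + (R_xlen_t)ng * (len - 1)] += 1.0;
        }
  }
  return counts;
}

// Size-zone enumeration: connected zones of equal level (given
// connectivity offsets, normally the 26-neighbourhood).  Returns a matrix
// with one row per zone: (level, size).
// [[Rcpp::export(name = ".cpp_glszm_zones")]]
IntegerMatrix cpp_glszm_zones(IntegerVector levels, IntegerVector dim,
                              IntegerMatrix offsets) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nd = offsets.nrow();
  std::vector<int> ox, oy, oz;
  copyOffsets(offsets, ox, oy, oz);
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> zlev, zsize;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (seen[start] || levels[start] == 0) continue;
    const int g = levels[start];
    int size = 0;
    seen[start] = 1;
    stack.clear();
    stack.push_back(start);
    while (!stack.empty()) {
      const R_xlen_t v = stack.back();
      stack.pop_back();
      ++size;
      const int x = (int)(v % nx);
      const int y = (int)((v / nx) % ny);
      const int z = (int)(v / ((R_xlen_t)nx * ny));
      for (int d = 0; d < nd; ++d) {
        const int x2 = x + ox[d], y2 = y + oy[d], z2 = z + oz[d];
        if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
          continue;
        const R_xlen_t w = idx3(x2, y2, z2, nx, ny);
        if (!seen[w] && levels[w] == g) {
          seen[w] = 1;
          stack.push_back(w);
        }
      }
    }
    zlev.push_back(g);
    zsize.push_back(size);
  }
  IntegerMatrix out((int)zlev.size(), 2);
  for (int i = 0; i < (int)zlev.size(); ++i) {
    out(i, 0) = zlev[i];
    out(i, 1) = zsize[i];
  }
  return out;
}

// Neighbouring gray-tone difference accumulation: per level i, the count
// n_i of in-ROI voxels with at least one in-ROI neighbour and the sum
// s_i of |i - mean neighbour level|.  Returns ng x 2 (n_i, s_i).
// [[Rcpp::export(name = ".cpp_ngtdm_counts")]]
NumericMatrix cpp_ngtdm_counts(IntegerVector levels, IntegerVector dim,
                               IntegerMatrix offsets, int ng) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nd = offsets.nrow();
  std::vector<int> ox, oy, oz;
  copyOffsets(offsets, ox, oy, oz);
  NumericMatrix out(ng, 2);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int gi = levels[idx3(x, y, z, nx, ny)];
        if (gi == 0) continue;
        double sum = 0.0;
        int cnt = 0;
        for (int d = 0; d < nd; ++d) {
          const int x2 = x + ox[d], y2 = y + oy[d], z2 = z + oz[d];
          if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
            continue;
          const int gj = levels[idx3(x2, y2, z2, nx, ny)];
          if (gj == 0) continue;
          sum += gj;
          ++cnt;
        }
        if (cnt > 0) {
          out(gi - 1, 0) += 1.0;
          out(gi - 1, 1) += std::fabs((double)gi - sum / cnt);
        }
      }
  return out;
}

// Connected-component labelling of a binary mask under an arbitrary
// neighbourhood (offsets).  Returns integer labels, 0 outside the mask.
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   IntegerMatrix offsets) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nd = offsets.nrow();
  std::vector<int> ox, oy, oz;
  copyOffsets(offsets, ox, oy, oz);
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(n, 0);
  const int *mp = LOGICAL(mask);
  int *lp = INTEGER(labels);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (mp[start] != 1 || lp[start] != 0) continue;
    ++next;
    lp[start] = next;
    stack.clear();
    stack.push_back(start);
    while (!stack.empty()) {
      const R_xlen_t v = stack.back();
      stack.pop_back();
      const int x = (int)(v % nx);
      const int y = (int)((v / nx) % ny);
      const int z = (int)(v / ((R_xlen_t)nx * ny));
      for (int d = 0; d < nd; ++d) {
        const int x2 = x + ox[d], y2 = y + oy[d], z2 = z + oz[d];
        if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
          continue;
        const R_xlen_t w = idx3(x2, y2, z2, nx, ny);
        if (mp[w] == 1 && lp[w] == 0) {
          lp[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  labels.attr("dim") = dim;
  return labels;
}

// Maximum pairwise Euclidean distance between points (rows of coords).
// [[Rcpp::export(name = ".cpp_max_pair_dist")]]
double cpp_max_pair_dist(NumericMatrix coords) {
  const int k = coords.nrow();
  if (k < 2) return 0.0;
  const int p = coords.ncol();
  double best = 0.0;
  for (int i = 0; i < k - 1; ++i)
    for (int j = i + 1; j < k; ++j) {
      double d2 = 0.0;
      for (int c = 0; c < p; ++c) {
        const double d = coords(i, c) - coords(j, c);
        d2 += d * d;
      }
      if (d2 > best) best = d2;
    }
  return std::sqrt(best);
}
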