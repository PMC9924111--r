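#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 3D connected-component labelling of a logical array (column-major,
// dims = c(nx, ny, nz)). connectivity: 6 (faces) or 26 (faces+edges+corners).
// Returns integer labels, 0 = background; labels are assigned in raster order
// of each component's first voxel, so the result is deterministic.
// [[Rcpp::export(name = ".cc_label3d")]]
IntegerVector cc_label3d(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");

  std::vector<int> off_x, off_y, off_z;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manhattan = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manhattan != 1) continue;
        off_x.push_back(dx); off_y.push_back(dy); off_z.push_back(dz);
      }
  const size_t noff = off_x.size();

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int next_label = 0;

  for (R_xlen_t seed = 0; seed < n; ++seed) {
    if (!mask[seed] || labels[seed] != 0) continue;
    ++next_label;
    labels[seed] = next_label;
    stack.clear();
    stack.push_back(seed);
    while (!stack.empty()) {
      R_xlen_t idx = stack.back();
      stack.pop_back();
      int x = (int)(idx % nx);
      int y = (int)((idx / nx) % ny);
      int z = (int)(idx / ((R_xlen_t)nx * ny));
      for (size_t k = 0; k < noff; ++k) {
        int xx = x + off_x[k], yy = y + off_y[k], zz = z + off_z[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        R_xlen_t nidx = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[nidx] && labels[nidx] == 0) {
          labels[nidx] = next_label;
          stack.push_back(nidx);
        }
      }
    }
  }
  return labels;
}

static inline double trilinear(const double* v, int nx, int ny, int nz,
                               double cx, double cy, double cz) {
  // continuous voxel index coordinates; outside the grid samples as 0
  if (cx < -0.5 || cy < -0.5 || cz < -0.5 ||
      cx > nx - 0.5 || cy > ny - 0.5 || cz > nz - 0.5) return 0.0;
  int x0 = (int)std::floor(cx), y0 = (int)std::floor(cy), z0 = (int)std::floor(cz);
  double fx = cx - x0, fy = cy - y0, fz = cz - z0;
  double acc = 0.0;
  for (int dz = 0; dz <= 1; ++dz) {
    int z = z0 + dz;
    if (z < 0 || z >= nz) continue;
    double wz = dz ? fz : 1.0 - fz;
    for (int dy = 0; dy <= 1; ++dy) {
      int y = y0 + dy;
      if (y < 0 || y >= ny) continue;
      double wy = dy ? fy : 1.0 - fy;
      for (int dx = 0; dx <= 1; ++dx) {
        int x = x0 + dx;
        if (x < 0 || x >= nx) continue;
        double wx = dx ? fx : 1.0 - fx;
        acc += wx * wy * wz * v[(R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x];
      }
    }
  }
  return acc;
}

// Radiological depth (g/cm^2 expressed as water-equivalent cm) from a point
// source to every voxel center: line integral of density along the straight
// ray, midpoint rule with fixed step (mm), trilinear density sampling.
// Only voxels where compute[idx] is TRUE are evaluated (others return 0).
// [[Rcpp::export(name = ".radiological_depth")]]
NumericVector radiological_depth(NumericVector density, IntegerVector dims,
                                 NumericVector spacing, NumericVector origin,
                                 NumericVector source, double step_mm,
                                 LogicalVector compute) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (density.size() != n || compute.size() != n) stop("array length mismatch");
  if (step_mm <= 0) stop("step_mm must be positive");
  const double* dens = REAL(density);
  NumericVector out(n, 0.0);

  // grid bounding box (voxel faces)
  double lo[3], hi[3];
  for (int i = 0; i < 3; ++i) {
    lo[i] = origin[i] - 0.5 * spacing[i];
    hi[i] = origin[i] + (dims[i] - 0.5) * spacing[i];
  }
  const double sx = source[0], sy = source[1], sz = source[2];

  for (int z = 0; z < nz; ++z) {
    double pz = origin[2] + z * spacing[2];
    for (int y = 0; y < ny; ++y) {
      double py = origin[1] + y * spacing[1];
      R_xlen_t row = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) {
        R_xlen_t idx = row + x;
        if (!compute[idx]) continue;
        double px = origin[0] + x * spacing[0];
        double dx = px - sx, dy = py - sy, dz = pz - sz;
        double L = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (L <= 0) continue;
        double ux = dx / L, uy = dy / L, uz = dz / L;
        // slab method: first t at which the ray enters the grid box
        double t_in = 0.0, t_out = L;
        double s0[3] = {sx, sy, sz}, u[3] = {ux, uy, uz};
        bool miss = false;
        for (int a = 0; a < 3; ++a) {
          if (std::fabs(u[a]) < 1e-12) {
            if (s0[a] < lo[a] || s0[a] > hi[a]) { miss = true; break; }
          } else {
            double t1 = (lo[a] - s0[a]) / u[a];
            double t2 = (hi[a] - s0[a]) / u[a];
            if (t1 > t2) std::swap(t1, t2);
            if (t1 > t_in) t_in = t1;
            if (t2 < t_out) t_out = t2;
          }
        }
        if (miss || t_in >= L) continue;
        double span = L - t_in;
        int nstep = (int)std::ceil(span / step_mm);
        if (nstep < 1) nstep = 1;
        double dt = span / nstep;
        double depth = 0.0;
        for (int k = 0; k < nstep; ++k) {
          double t = t_in + (k + 0.5) * dt;
          double cxp = (sx + t * ux - origin[0]) / spacing[0];
          double cyp = (sy + t * uy - origin[1]) / spacing[1];
          double czp = (sz + t * uz - origin[2]) / spacing[2];
          depth += trilinear(dens, nx, ny, nz, cxp, cyp, czp) * dt;
        }
        out[idx] = depth / 10.0; // mm -> cm of water-equivalent path
      }
    }
  }
  return out;
}
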