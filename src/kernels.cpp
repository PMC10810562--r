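#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
#include <algorithm>
using namespace Rcpp;

// ---- separable 3D Gaussian blur -------------------------------------------
// Truncated at 4 sigma, kernel renormalised, reflecting boundaries.
// Sigmas are in voxel units per axis; sigma <= 0 skips that axis.

static inline int reflect_idx(int p, int len) {
  if (p < 0) p = -p - 1;
  if (p >= len) p = 2 * len - p - 1;
  if (p < 0) p = 0;
  if (p >= len) p = len - 1;
  return p;
}

// Cache-friendly: the x-contiguous inner loop is preserved for every axis by
// accumulating shifted whole rows instead of gathering along strided lines.
static void blur_axis(std::vector<double> &v, std::vector<double> &tmp,
                      int nx, int ny, int nz, int axis, double sigma) {
  if (sigma <= 0) return;
  int rad = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * rad + 1);
  double s = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    k[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + rad];
  }
  for (double &w : k) w /= s;
  long nxy = (long)nx * ny;
  std::fill(tmp.begin(), tmp.end(), 0.0);
  if (axis == 0) {
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        const double *in = &v[(long)y * nx + z * nxy];
        double *out = &tmp[(long)y * nx + z * nxy];
        for (int x = 0; x < nx; ++x) {
          double acc = 0.0;
          if (x >= rad && x + rad < nx) {
            for (int j = -rad; j <= rad; ++j) acc += k[j + rad] * in[x + j];
          } else {
            for (int j = -rad; j <= rad; ++j)
              acc += k[j + rad] * in[reflect_idx(x + j, nx)];
          }
          out[x] = acc;
        }
      }
  } else {
    int len = (axis == 1) ? ny : nz;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        double *out = &tmp[(long)y * nx + z * nxy];
        for (int j = -rad; j <= rad; ++j) {
          int p = reflect_idx(((axis == 1) ? y : z) + j, len);
          const double *in = (axis == 1) ? &v[(long)p * nx + z * nxy]
                                         : &v[(long)y * nx + p * nxy];
          double w = k[j + rad];
          for (int x = 0; x < nx; ++x) out[x] += w * in[x];
        }
      }
  }
  v.swap(tmp);
}

// ---- analytic Gaussian spots ----------------------------------------------
// Adds intens[i] * discrete 3D Gaussian (sigmas in voxels) centered at the
// continuous 0-based position pos[i,], truncated at 4 sigma.  The discrete
// kernel is normalised so the deposited mass equals intens[i] (up to edge
// clipping), matching a delta deposit followed by a normalised blur.

// [[Rcpp::export(name = ".cpp_add_gaussians")]]
NumericVector cpp_add_gaussians(NumericVector arr, IntegerVector dim,
                                NumericMatrix pos, NumericVector intens,
                                double sx, double sy, double sz) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out = clone(arr);
  int rx = (int)std::ceil(4 * sx), ry = (int)std::ceil(4 * sy),
      rz = (int)std::ceil(4 * sz);
  for (int i = 0; i < pos.nrow(); ++i) {
    double cx = pos(i, 0), cy = pos(i, 1), cz = pos(i, 2);
    int x0 = (int)std::floor(cx) - rx, x1 = (int)std::ceil(cx) + rx;
    int y0 = (int)std::floor(cy) - ry, y1 = (int)std::ceil(cy) + ry;
    int z0 = (int)std::floor(cz) - rz, z1 = (int)std::ceil(cz) + rz;
    // per-axis weights (normalised over the full window, pre-clipping)
    std::vector<double> wx(x1 - x0 + 1), wy(y1 - y0 + 1), wz(z1 - z0 + 1);
    double sxs = 0, sys = 0, szs = 0;
    for (int x = x0; x <= x1; ++x)
      sxs += (wx[x - x0] = std::exp(-0.5 * (x - cx) * (x - cx) / (sx * sx)));
    for (int y = y0; y <= y1; ++y)
      sys += (wy[y - y0] = std::exp(-0.5 * (y - cy) * (y - cy) / (sy * sy)));
    for (int z = z0; z <= z1; ++z)
      szs += (wz[z - z0] = std::exp(-0.5 * (z - cz) * (z - cz) / (sz * sz)));
    double norm = intens[i] / (sxs * sys * szs);
    for (int z = std::max(0, z0); z <= std::min(nz - 1, z1); ++z)
      for (int y = std::max(0, y0); y <= std::min(ny - 1, y1); ++y) {
        double wzy = wz[z - z0] * wy[y - y0] * norm;
        double *row = &out[(long)nx * y + (long)nx * ny * z];
        for (int x = std::max(0, x0); x <= std::min(nx - 1, x1); ++x)
          row[x] += wzy * wx[x - x0];
      }
  }
  out.attr("dim") = dim;
  return out;
}

// [[Rcpp::export(name = ".cpp_blur3d")]]
NumericVector cpp_blur3d(NumericVector arr, IntegerVector dim,
                         double sx, double sy, double sz) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> v(arr.begin(), arr.end()), tmp(v.size());
  blur_axis(v, tmp, nx, ny, nz, 0, sx);
  blur_axis(v, tmp, nx, ny, nz, 1, sy);
  blur_axis(v, tmp, nx, ny, nz, 2, sz);
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dim;
  return out;
}

// ---- rasterise nuclei / membrane objects ----------------------------------
// Objects are rows of a matrix, all geometry in continuous voxel coordinates
// (0-based). Columns:
//  0 type: 0 = sphere with optional dark core, 1 = xy-rotated ellipsoid,
//          2 = crescent (sphere minus an offset sphere)
//  1-3 cx, cy, cz
//  4-6 rx, ry, rz          (semi-axes)
//  7   theta               (xy-plane rotation, radians; type 1 only)
//  8   amp                 (added intensity inside the body)
//  9-10 core_rxy, core_rz  (dark-core semi-axes; 0 = none)
// 11   core_frac           (multiplier inside the core / removed lune)
// 12-14 ox, oy, oz         (offset of the subtracted sphere; type 2)
// 15-16 sub_rxy, sub_rz    (semi-axes of the subtracted sphere; type 2)
// Values combine by max() so adjacent nuclei do not stack intensity.

// [[Rcpp::export(name = ".cpp_raster_objects")]]
NumericVector cpp_raster_objects(NumericVector arr, IntegerVector dim,
                                 NumericMatrix obj) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out = clone(arr);
  for (int o = 0; o < obj.nrow(); ++o) {
    int type = (int)obj(o, 0);
    double cx = obj(o, 1), cy = obj(o, 2), cz = obj(o, 3);
    double rx = obj(o, 4), ry = obj(o, 5), rz = obj(o, 6);
    double th = obj(o, 7), amp = obj(o, 8);
    double crxy = obj(o, 9), crz = obj(o, 10), cfrac = obj(o, 11);
    double ox = obj(o, 12), oy = obj(o, 13), oz = obj(o, 14);
    double srxy = obj(o, 15), srz = obj(o, 16);
    double rmax = std::max(rx, std::max(ry, rz));
    int x0 = std::max(0, (int)std::floor(cx - rmax - 1));
    int x1 = std::min(nx - 1, (int)std::ceil(cx + rmax + 1));
    int y0 = std::max(0, (int)std::floor(cy - rmax - 1));
    int y1 = std::min(ny - 1, (int)std::ceil(cy + rmax + 1));
    int z0 = std::max(0, (int)std::floor(cz - rmax - 1));
    int z1 = std::min(nz - 1, (int)std::ceil(cz + rmax + 1));
    double ct = std::cos(th), st = std::sin(th);
    for (int z = z0; z <= z1; ++z) {
      for (int y = y0; y <= y1; ++y) {
        for (int x = x0; x <= x1; ++x) {
          double dx = x - cx, dy = y - cy, dz = z - cz;
          double u = dx, w = dy;
          if (type == 1) { u = ct * dx + st * dy; w = -st * dx + ct * dy; }
          double q = (u * u) / (rx * rx) + (w * w) / (ry * ry) +
                     (dz * dz) / (rz * rz);
          if (q > 1.0) continue;
          double val = amp;
          if (type == 2 && srxy > 0) {
            double ex = dx - ox, ey = dy - oy, ez = dz - oz;
            double qs = (ex * ex + ey * ey) / (srxy * srxy) +
                        (ez * ez) / (srz * srz);
            if (qs <= 1.0) val = amp * cfrac;   // carved-out lune
          } else if (crxy > 0) {
            double qc = (dx * dx + dy * dy) / (crxy * crxy) +
                        (dz * dz) / (crz * crz);
            if (qc <= 1.0) val = amp * cfrac;   // dark nucleolar core
          }
          long idx = x + (long)nx * y + (long)nx * ny * z;
          if (val > out[idx]) out[idx] = val;
        }
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// ---- trilinear point deposition -------------------------------------------
// Adds `intens[i]` spread over the 8 voxels surrounding continuous voxel
// coordinate pos[i,] (0-based); total deposited mass is preserved, so a
// later normalised blur leaves spot integrals equal to `intens`.

// [[Rcpp::export(name = ".cpp_add_points")]]
NumericVector cpp_add_points(NumericVector arr, IntegerVector dim,
                             NumericMatrix pos, NumericVector intens) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out = clone(arr);
  for (int i = 0; i < pos.nrow(); ++i) {
    double x = pos(i, 0), y = pos(i, 1), z = pos(i, 2);
    int ix = (int)std::floor(x), iy = (int)std::floor(y), iz = (int)std::floor(z);
    double fx = x - ix, fy = y - iy, fz = z - iz;
    for (int dz = 0; dz <= 1; ++dz)
      for (int dy = 0; dy <= 1; ++dy)
        for (int dx = 0; dx <= 1; ++dx) {
          int px = ix + dx, py = iy + dy, pz = iz + dz;
          if (px < 0 || px >= nx || py < 0 || py >= ny || pz < 0 || pz >= nz)
            continue;
          double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) * (dz ? fz : 1 - fz);
          out[px + (long)nx * py + (long)nx * ny * pz] += w * intens[i];
        }
  }
  out.attr("dim") = dim;
  return out;
}

// ---- circular Hough transform with gradient voting ------------------------
// Sobel gradients; pixels above gradThresh vote along +/- the gradient
// direction at integer radii rmin..rmax.  Accumulator planes are box-smoothed
// and candidate circles are 3x3x(r+/-1) local maxima whose score
// (votes / circumference) exceeds `sensitivity`.  Centers are refined by a
// 3x3 centroid, radii by a 3-point parabola.  Returns cols x, y, r, score
// (x, y, r in pixels, 0-based centers).

// [[Rcpp::export(name = ".cpp_hough_circles")]]
NumericMatrix cpp_hough_circles(NumericMatrix img, double rmin, double rmax,
                                double gradThresh, double sensitivity,
                                int rstep = 2) {
  int nx = img.nrow(), ny = img.ncol();
  int r0 = (int)std::floor(rmin), r1 = (int)std::ceil(rmax);
  int nr = (r1 - r0) / rstep + 1;
  std::vector<float> acc((size_t)nx * ny * nr, 0.0f);
  // Sobel
  for (int y = 1; y < ny - 1; ++y) {
    for (int x = 1; x < nx - 1; ++x) {
      double gx = img(x + 1, y - 1) + 2 * img(x + 1, y) + img(x + 1, y + 1)
                - img(x - 1, y - 1) - 2 * img(x - 1, y) - img(x - 1, y + 1);
      double gy = img(x - 1, y + 1) + 2 * img(x, y + 1) + img(x + 1, y + 1)
                - img(x - 1, y - 1) - 2 * img(x, y - 1) - img(x + 1, y - 1);
      double mag = std::sqrt(gx * gx + gy * gy);
      if (mag < gradThresh) continue;
      double ux = gx / mag, uy = gy / mag;
      for (int t = 0; t < nr; ++t) {
        double r = r0 + t * rstep;
        for (int sgn = -1; sgn <= 1; sgn += 2) {
          int vx = (int)std::lround(x + sgn * r * ux);
          int vy = (int)std::lround(y + sgn * r * uy);
          if (vx >= 0 && vx < nx && vy >= 0 && vy < ny)
            acc[(size_t)vx + (size_t)nx * vy + (size_t)nx * ny * t] += 1.0f;
        }
      }
    }
  }
  // 3x3 box smooth per radius plane
  std::vector<float> sm(acc.size());
  for (int pass = 0; pass < 1; ++pass) {
    for (int t = 0; t < nr; ++t) {
      size_t off = (size_t)nx * ny * t;
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          float s = 0.0f; int n = 0;
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              int px = x + dx, py = y + dy;
              if (px < 0 || px >= nx || py < 0 || py >= ny) continue;
              s += acc[off + px + (size_t)nx * py]; ++n;
            }
          sm[off + x + (size_t)nx * y] = s / n;
        }
    }
    acc.swap(sm);
  }
  // candidate peaks
  std::vector<double> res;
  for (int t = 0; t < nr; ++t) {
    double r = r0 + t * rstep;
    double norm = 2.0 * M_PI * r;
    size_t off = (size_t)nx * ny * t;
    for (int y = 1; y < ny - 1; ++y) {
      for (int x = 1; x < nx - 1; ++x) {
        float v = acc[off + x + (size_t)nx * y];
        if (v / norm < sensitivity) continue;
        bool ismax = true;
        for (int dt = -1; dt <= 1 && ismax; ++dt) {
          int tt = t + dt;
          if (tt < 0 || tt >= nr) continue;
          size_t o2 = (size_t)nx * ny * tt;
          for (int dy = -1; dy <= 1 && ismax; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dt == 0 && dx == 0 && dy == 0) continue;
              float w = acc[o2 + (x + dx) + (size_t)nx * (y + dy)];
              if (w > v || (w == v && (dt < 0 || (dt == 0 && (dy < 0 || (dy == 0 && dx < 0)))))) {
                ismax = false; break;
              }
            }
        }
        if (!ismax) continue;
        // centroid refinement in the plane
        double sw = 0, sx = 0, sy = 0;
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            double w = acc[off + (x + dx) + (size_t)nx * (y + dy)];
            sw += w; sx += w * (x + dx); sy += w * (y + dy);
          }
        double px = sw > 0 ? sx / sw : x, py = sw > 0 ? sy / sw : y;
        // parabolic radius refinement
        double rr = r;
        if (t > 0 && t < nr - 1) {
          double vm = acc[(size_t)nx * ny * (t - 1) + x + (size_t)nx * y];
          double vp = acc[(size_t)nx * ny * (t + 1) + x + (size_t)nx * y];
          double den = vm - 2.0 * v + vp;
          if (den < 0) rr = r + 0.5 * (vm - vp) / den * rstep;
        }
        res.push_back(px); res.push_back(py); res.push_back(rr);
        res.push_back(v / norm);
      }
    }
  }
  int ncand = res.size() / 4;
  NumericMatrix out(ncand, 4);
  for (int i = 0; i < ncand; ++i)
    for (int j = 0; j < 4; ++j) out(i, j) = res[4 * i + j];
  colnames(out) = CharacterVector::create("x", "y", "r", "score");
  return out;
}

// ---- 3D local maxima -------------------------------------------------------
// Voxels strictly greater than all 26 neighbours and > floor.
// Returns cols ix, iy, iz (1-based) and value.

// [[Rcpp::export(name = ".cpp_local_maxima3d")]]
NumericMatrix cpp_local_maxima3d(NumericVector arr, IntegerVector dim,
                                 double floorVal) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> res;
  for (int z = 1; z < nz - 1; ++z)
    for (int y = 1; y < ny - 1; ++y)
      for (int x = 1; x < nx - 1; ++x) {
        double v = arr[x + (long)nx * y + (long)nx * ny * z];
        if (v <= floorVal) continue;
        bool ismax = true;
        for (int dz = -1; dz <= 1 && ismax; ++dz)
          for (int dy = -1; dy <= 1 && ismax; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              if (arr[(x + dx) + (long)nx * (y + dy) + (long)nx * ny * (z + dz)] >= v) {
                ismax = false; break;
              }
            }
        if (ismax) {
          res.push_back(x + 1); res.push_back(y + 1); res.push_back(z + 1);
          res.push_back(v);
        }
      }
  int n = res.size() / 4;
  NumericMatrix out(n, 4);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 4; ++j) out(i, j) = res[4 * i + j];
  colnames(out) = CharacterVector::create("ix", "iy", "iz", "value");
  return out;
}

// ---- 3D connected-component labelling (26-neighbourhood) -------------------

// [[Rcpp::export(name = ".cpp_label3d")]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long n = (long)nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<long> stack;
  for (long i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    stack.clear();
    stack.push_back(i);
    lab[i] = next;
    while (!stack.empty()) {
      long cur = stack.back(); stack.pop_back();
      int x = cur % nx, y = (cur / nx) % ny, z = cur / ((long)nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int px = x + dx, py = y + dy, pz = z + dz;
            if (px < 0 || px >= nx || py < 0 || py >= ny || pz < 0 || pz >= nz)
              continue;
            long q = px + (long)nx * py + (long)nx * ny * pz;
            if (mask[q] && !lab[q]) { lab[q] = next; stack.push_back(q); }
          }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// ---- summed intensity inside an ellipsoidal ball ---------------------------
// Sum of voxels whose centers lie inside the axis-aligned ellipsoid with
// semi-axes (rxy, rxy, rz) voxels around continuous 0-based center c.
// Guarantees at least the containing voxel is counted.

// [[Rcpp::export(name = ".cpp_ball_sum")]]
NumericVector cpp_ball_sum(NumericVector arr, IntegerVector dim,
                           NumericMatrix centers, double rxy, double rz) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int nc = centers.nrow();
  NumericVector sums(nc), counts(nc);
  for (int i = 0; i < nc; ++i) {
    double cx = centers(i, 0), cy = centers(i, 1), cz = centers(i, 2);
    int x0 = std::max(0, (int)std::floor(cx - rxy)), x1 = std::min(nx - 1, (int)std::ceil(cx + rxy));
    int y0 = std::max(0, (int)std::floor(cy - rxy)), y1 = std::min(ny - 1, (int)std::ceil(cy + rxy));
    int z0 = std::max(0, (int)std::floor(cz - rz)), z1 = std::min(nz - 1, (int)std::ceil(cz + rz));
    double s = 0; long cnt = 0;
    for (int z = z0; z <= z1; ++z)
      for (int y = y0; y <= y1; ++y)
        for (int x = x0; x <= x1; ++x) {
          double q = ((x - cx) * (x - cx) + (y - cy) * (y - cy)) / (rxy * rxy)
                   + ((z - cz) * (z - cz)) / (rz * rz);
          if (q <= 1.0) { s += arr[x + (long)nx * y + (long)nx * ny * z]; ++cnt; }
        }
    if (cnt == 0) {   // degenerate radius: containing voxel
      int x = std::min(nx - 1, std::max(0, (int)std::lround(cx)));
      int y = std::min(ny - 1, std::max(0, (int)std::lround(cy)));
      int z = std::min(nz - 1, std::max(0, (int)std::lround(cz)));
      s = arr[x + (long)nx * y + (long)nx * ny * z]; cnt = 1;
    }
    sums[i] = s; counts[i] = cnt;
  }
  NumericVector out(2 * nc);
  for (int i = 0; i < nc; ++i) { out[i] = sums[i]; out[nc + i] = counts[i]; }
  out.attr("dim") = IntegerVector::create(nc, 2);
  return out;
}

// ---- Poisson + Gaussian read noise in one pass -----------------------------
// Uses R's RNG stream, so set.seed() determinism is preserved.

// [[Rcpp::export(name = ".cpp_apply_noise")]]
NumericVector cpp_apply_noise(NumericVector arr, double readSd) {
  NumericVector out(arr.size());
  GetRNGstate();
  for (R_xlen_t i = 0; i < arr.size(); ++i) {
    double v = R::rpois(arr[i] > 0 ? arr[i] : 0.0);
    if (readSd > 0) v += R::rnorm(0.0, readSd);
    v = std::floor(v + 0.5);
    out[i] = v > 0 ? v : 0.0;
  }
  PutRNGstate();
  out.attr("dim") = arr.attr("dim");
  return out;
}
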