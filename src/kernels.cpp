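// Low-level raster kernels: trilinear sampling/warping, grid resampling,
// exact anisotropic distance transforms, connected components, separable
// Gaussian blur, and the 3D convolution forward/backward passes used by the
// deformation-field network. All arrays are R column-major; volumes are
// indexed [x, y, z] and channel stacks [x, y, z, c].
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static inline R_xlen_t idx3(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// Trilinear sample at continuous 0-based index (x,y,z); fill outside the grid.
static double sample3(const double* a, int nx, int ny, int nz,
                      double x, double y, double z, double fill, bool clamp) {
  if (clamp) {
    if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
    if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
    if (z < 0) z = 0; if (z > nz - 1) z = nz - 1;
  } else if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
    return fill;
  }
  // exact-integer coordinates (e.g. the zero field) sample bitwise
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  int x1 = x0 + 1 > nx - 1 ? x0 : x0 + 1;
  int y1 = y0 + 1 > ny - 1 ? y0 : y0 + 1;
  int z1 = z0 + 1 > nz - 1 ? z0 : z0 + 1;
  double c000 = a[idx3(x0, y0, z0, nx, ny)], c100 = a[idx3(x1, y0, z0, nx, ny)];
  double c010 = a[idx3(x0, y1, z0, nx, ny)], c110 = a[idx3(x1, y1, z0, nx, ny)];
  double c001 = a[idx3(x0, y0, z1, nx, ny)], c101 = a[idx3(x1, y0, z1, nx, ny)];
  double c011 = a[idx3(x0, y1, z1, nx, ny)], c111 = a[idx3(x1, y1, z1, nx, ny)];
  double c00 = fx == 0 ? c000 : c000 + fx * (c100 - c000);
  double c10 = fx == 0 ? c010 : c010 + fx * (c110 - c010);
  double c01 = fx == 0 ? c001 : c001 + fx * (c101 - c001);
  double c11 = fx == 0 ? c011 : c011 + fx * (c111 - c011);
  double c0 = fy == 0 ? c00 : c00 + fy * (c10 - c00);
  double c1 = fy == 0 ? c01 : c01 + fy * (c11 - c01);
  return fz == 0 ? c0 : c0 + fz * (c1 - c0);
}

// [[Rcpp::export]]
NumericVector cpp_warp(NumericVector mov, IntegerVector dim,
                       NumericVector ux, NumericVector uy, NumericVector uz,
                       NumericVector spacing, double fill, bool clamp = false) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(mov.size());
  const double* a = mov.begin();
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  R_xlen_t p = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++p) {
        double x = i + ux[p] / sx, y = j + uy[p] / sy, z = k + uz[p] / sz;
        out[p] = sample3(a, nx, ny, nz, x, y, z, fill, clamp);
      }
  out.attr("dim") = dim;
  return out;
}

// Gradient of warp output w.r.t. the displacement components (mm), chained
// with upstream gradient gout. Out-of-bounds samples contribute zero.
// [[Rcpp::export]]
List cpp_warp_grad(NumericVector mov, IntegerVector dim,
                   NumericVector ux, NumericVector uy, NumericVector uz,
                   NumericVector spacing, NumericVector gout, bool clamp = false) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector gx(mov.size()), gy(mov.size()), gz(mov.size());
  const double* a = mov.begin();
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  R_xlen_t p = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++p) {
        double g = gout[p];
        if (g == 0.0) continue;
        double x = i + ux[p] / sx, y = j + uy[p] / sy, z = k + uz[p] / sz;
        bool cx = false, cy = false, cz = false;
        if (clamp) {
          if (x < 0) { x = 0; cx = true; } else if (x > nx - 1) { x = nx - 1; cx = true; }
          if (y < 0) { y = 0; cy = true; } else if (y > ny - 1) { y = ny - 1; cy = true; }
          if (z < 0) { z = 0; cz = true; } else if (z > nz - 1) { z = nz - 1; cz = true; }
        } else if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
          continue;
        }
        int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
        if (x0 > nx - 2) x0 = nx > 1 ? nx - 2 : 0;
        if (y0 > ny - 2) y0 = ny > 1 ? ny - 2 : 0;
        if (z0 > nz - 2) z0 = nz > 1 ? nz - 2 : 0;
        double fx = x - x0, fy = y - y0, fz = z - z0;
        int x1 = x0 + 1, y1 = y0 + 1, z1 = z0 + 1;
        if (nx == 1) x1 = x0;
        if (ny == 1) y1 = y0;
        if (nz == 1) z1 = z0;
        double c000 = a[idx3(x0, y0, z0, nx, ny)], c100 = a[idx3(x1, y0, z0, nx, ny)];
        double c010 = a[idx3(x0, y1, z0, nx, ny)], c110 = a[idx3(x1, y1, z0, nx, ny)];
        double c001 = a[idx3(x0, y0, z1, nx, ny)], c101 = a[idx3(x1, y0, z1, nx, ny)];
        double c011 = a[idx3(x0, y1, z1, nx, ny)], c111 = a[idx3(x1, y1, z1, nx, ny)];
        double dx = (1 - fy) * (1 - fz) * (c100 - c000) + fy * (1 - fz) * (c110 - c010)
                  + (1 - fy) * fz * (c101 - c001) + fy * fz * (c111 - c011);
        double dy = (1 - fx) * (1 - fz) * (c010 - c000) + fx * (1 - fz) * (c110 - c100)
                  + (1 - fx) * fz * (c011 - c001) + fx * fz * (c111 - c101);
        double dz = (1 - fx) * (1 - fy) * (c001 - c000) + fx * (1 - fy) * (c101 - c100)
                  + (1 - fx) * fy * (c011 - c010) + fx * fy * (c111 - c110);
        gx[p] = cx ? 0.0 : g * dx / sx;
        gy[p] = cy ? 0.0 : g * dy / sy;
        gz[p] = cz ? 0.0 : g * dz / sz;
      }
  gx.attr("dim") = dim; gy.attr("dim") = dim; gz.attr("dim") = dim;
  return List::create(_["x"] = gx, _["y"] = gy, _["z"] = gz);
}

// Resample arr (with its own spacing/origin) onto an output grid given by
// out_dim/out_spacing/out_origin. clamp=TRUE replicates the border (used by
// field-of-view preserving resizes so constants stay exact); clamp=FALSE
// fills out-of-bounds with `fill`.
// [[Rcpp::export]]
NumericVector cpp_resample_grid(NumericVector arr, IntegerVector dim,
                                NumericVector in_spacing, NumericVector in_origin,
                                IntegerVector out_dim, NumericVector out_spacing,
                                NumericVector out_origin,
                                bool nearest, bool clamp, double fill) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int mx = out_dim[0], my = out_dim[1], mz = out_dim[2];
  NumericVector out((R_xlen_t)mx * my * mz);
  const double* a = arr.begin();
  // continuous input index of output voxel i along axis d:
  //   (out_origin + i*out_spacing - in_origin) / in_spacing
  std::vector<double> xi(mx), yj(my), zk(mz);
  for (int i = 0; i < mx; ++i) xi[i] = (out_origin[0] + i * out_spacing[0] - in_origin[0]) / in_spacing[0];
  for (int j = 0; j < my; ++j) yj[j] = (out_origin[1] + j * out_spacing[1] - in_origin[1]) / in_spacing[1];
  for (int k = 0; k < mz; ++k) zk[k] = (out_origin[2] + k * out_spacing[2] - in_origin[2]) / in_spacing[2];
  R_xlen_t p = 0;
  for (int k = 0; k < mz; ++k)
    for (int j = 0; j < my; ++j)
      for (int i = 0; i < mx; ++i, ++p) {
        double x = xi[i], y = yj[j], z = zk[k];
        if (nearest) {
          long ri = std::lround(x), rj = std::lround(y), rk = std::lround(z);
          if (clamp) {
            if (ri < 0) ri = 0; if (ri > nx - 1) ri = nx - 1;
            if (rj < 0) rj = 0; if (rj > ny - 1) rj = ny - 1;
            if (rk < 0) rk = 0; if (rk > nz - 1) rk = nz - 1;
          } else if (ri < 0 || rj < 0 || rk < 0 || ri > nx - 1 || rj > ny - 1 || rk > nz - 1) {
            out[p] = fill; continue;
          }
          out[p] = a[idx3((int)ri, (int)rj, (int)rk, nx, ny)];
        } else {
          out[p] = sample3(a, nx, ny, nz, x, y, z, fill, clamp);
        }
      }
  out.attr("dim") = out_dim;
  return out;
}

// Resample under a rigid map: output(p) = input(T^{-1}(p)) with
// T(q) = R (q - c) + c + t, R = Rz Ry Rx (degrees), c = grid centre (mm).
// [[Rcpp::export]]
NumericVector cpp_rigid_resample(NumericVector arr, IntegerVector dim,
                                 NumericVector spacing, NumericVector rot_deg,
                                 NumericVector trans_mm, double fill, bool nearest) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(arr.size());
  const double* a = arr.begin();
  double d2r = M_PI / 180.0;
  double ax = rot_deg[0] * d2r, ay = rot_deg[1] * d2r, az = rot_deg[2] * d2r;
  double cx = std::cos(ax), sxn = std::sin(ax);
  double cy = std::cos(ay), syn = std::sin(ay);
  double cz = std::cos(az), szn = std::sin(az);
  // R = Rz * Ry * Rx
  double R[3][3] = {
    {cz * cy, cz * syn * sxn - szn * cx, cz * syn * cx + szn * sxn},
    {szn * cy, szn * syn * sxn + cz * cx, szn * syn * cx - cz * sxn},
    {-syn, cy * sxn, cy * cx}};
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  double c0 = 0.5 * (nx - 1) * sx, c1 = 0.5 * (ny - 1) * sy, c2 = 0.5 * (nz - 1) * sz;
  R_xlen_t p = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++p) {
        double px = i * sx - c0 - trans_mm[0];
        double py = j * sy - c1 - trans_mm[1];
        double pz = k * sz - c2 - trans_mm[2];
        // q = R^T p + c  (inverse rotation)
        double qx = R[0][0] * px + R[1][0] * py + R[2][0] * pz + c0;
        double qy = R[0][1] * px + R[1][1] * py + R[2][1] * pz + c1;
        double qz = R[0][2] * px + R[1][2] * py + R[2][2] * pz + c2;
        double x = qx / sx, y = qy / sy, z = qz / sz;
        if (nearest) {
          long ri = std::lround(x), rj = std::lround(y), rk = std::lround(z);
          out[p] = (ri < 0 || rj < 0 || rk < 0 || ri > nx - 1 || rj > ny - 1 || rk > nz - 1)
                     ? fill : a[idx3((int)ri, (int)rj, (int)rk, nx, ny)];
        } else {
          out[p] = sample3(a, nx, ny, nz, x, y, z, fill, false);
        }
      }
  out.attr("dim") = dim;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_sample_points(NumericVector arr, IntegerVector dim,
                                NumericMatrix pts, double fill) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = pts.nrow();
  NumericVector out(n);
  for (int r = 0; r < n; ++r)
    out[r] = sample3(arr.begin(), nx, ny, nz, pts(r, 0), pts(r, 1), pts(r, 2), fill, false);
  return out;
}

// ---- exact Euclidean distance transform (Felzenszwalb & Huttenlocher) ----
static void dt1d(const double* f, double* d, int n, double s2,
                 std::vector<int>& v, std::vector<double>& zb) {
  int k = 0;
  v[0] = 0; zb[0] = -HUGE_VAL; zb[1] = HUGE_VAL;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) / (2.0 * s2 * (q - p));
      if (s <= zb[k]) { --k; } else break;
    }
    ++k; v[k] = q; zb[k] = s; zb[k + 1] = HUGE_VAL;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    int p = v[k];
    d[q] = s2 * (q - p) * (q - p) + f[p];
  }
}

// Distance (mm) from every voxel to the nearest mask==1 voxel centre.
// [[Rcpp::export]]
NumericVector cpp_edt(IntegerVector mask, IntegerVector dim, NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double FARV = 1e20;   // finite sentinel keeps the parabola math valid
  std::vector<double> d(n);
  for (R_xlen_t p = 0; p < n; ++p) d[p] = mask[p] ? 0.0 : FARV;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), dd(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);
  // x pass
  double s2 = spacing[0] * spacing[0];
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = idx3(0, j, k, nx, ny);
      for (int i = 0; i < nx; ++i) f[i] = d[base + i];
      dt1d(f.data(), dd.data(), nx, s2, v, zb);
      for (int i = 0; i < nx; ++i) d[base + i] = dd[i];
    }
  // y pass
  s2 = spacing[1] * spacing[1];
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = d[idx3(i, j, k, nx, ny)];
      dt1d(f.data(), dd.data(), ny, s2, v, zb);
      for (int j = 0; j < ny; ++j) d[idx3(i, j, k, nx, ny)] = dd[j];
    }
  // z pass
  s2 = spacing[2] * spacing[2];
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = d[idx3(i, j, k, nx, ny)];
      dt1d(f.data(), dd.data(), nz, s2, v, zb);
      for (int k = 0; k < nz; ++k) d[idx3(i, j, k, nx, ny)] = dd[k];
    }
  NumericVector out(n);
  for (R_xlen_t p = 0; p < n; ++p)
    out[p] = d[p] >= 1e19 ? R_PosInf : std::sqrt(d[p]);
  out.attr("dim") = dim;
  return out;
}

// 3D connected components; connectivity 6 or 26. Labels start at 1 in scan
// order, 0 = background.
// [[Rcpp::export]]
IntegerVector cpp_label3d(IntegerVector mask, IntegerVector dim, int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      int i = (int)(p % nx), j = (int)((p / nx) % ny), k = (int)(p / ((R_xlen_t)nx * ny));
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            if (connectivity == 6 && std::abs(di) + std::abs(dj) + std::abs(dk) > 1) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
            R_xlen_t q = idx3(ii, jj, kk, nx, ny);
            if (mask[q] && !lab[q]) { lab[q] = next; stack.push_back(q); }
          }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// 2D 8-connected components on a matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_label2d(IntegerMatrix mask) {
  int nx = mask.nrow(), ny = mask.ncol();
  IntegerMatrix lab(nx, ny);
  std::vector<std::pair<int, int>> stack;
  int next = 0;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      lab(i, j) = next;
      stack.push_back({i, j});
      while (!stack.empty()) {
        auto pr = stack.back(); stack.pop_back();
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            int ii = pr.first + di, jj = pr.second + dj;
            if (ii < 0 || jj < 0 || ii >= nx || jj >= ny) continue;
            if (mask(ii, jj) && !lab(ii, jj)) { lab(ii, jj) = next; stack.push_back({ii, jj}); }
          }
      }
    }
  return lab;
}

// Separable Gaussian blur, replicate boundary; sigma in voxels per axis.
// [[Rcpp::export]]
NumericVector cpp_gauss_blur(NumericVector arr, IntegerVector dim, NumericVector sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(arr.begin(), arr.end()), b(n);
  int dims[3] = {nx, ny, nz};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> kern(2 * r + 1);
    double tot = 0;
    for (int t = -r; t <= r; ++t) { kern[t + r] = std::exp(-0.5 * t * t / (s * s)); tot += kern[t + r]; }
    for (auto& w : kern) w /= tot;
    R_xlen_t stride = ax == 0 ? 1 : (ax == 1 ? nx : (R_xlen_t)nx * ny);
    int len = dims[ax];
    R_xlen_t p = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i, ++p) {
          int pos = ax == 0 ? i : (ax == 1 ? j : k);
          double acc = 0;
          for (int t = -r; t <= r; ++t) {
            int q = pos + t;
            if (q < 0) q = 0;
            if (q > len - 1) q = len - 1;
            acc += kern[t + r] * a[p + (R_xlen_t)(q - pos) * stride];
          }
          b[p] = acc;
        }
    a.swap(b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// ---- 3D convolution (3x3x3, stride 1, zero pad 1) for the DVF network ----
// x: [nx,ny,nz,ci], w: [3,3,3,ci,co], b: [co] -> y: [nx,ny,nz,co]
// [[Rcpp::export]]
NumericVector cpp_conv3d(NumericVector x, IntegerVector dim, int ci,
                         NumericVector w, NumericVector b, int co) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t vol = (R_xlen_t)nx * ny * nz;
  NumericVector y(vol * co);
  const double* xp = x.begin();
  const double* wp = w.begin();
  for (int oc = 0; oc < co; ++oc) {
    double* yp = y.begin() + vol * oc;
    for (R_xlen_t p = 0; p < vol; ++p) yp[p] = b[oc];
    for (int icc = 0; icc < ci; ++icc) {
      const double* xc = xp + vol * icc;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            // w index: [dx+1, dy+1, dz+1, icc, oc]
            double wv = wp[(dx + 1) + 3 * ((dy + 1) + 3 * ((dz + 1) + 3 * ((R_xlen_t)icc + (R_xlen_t)ci * oc)))];
            if (wv == 0.0) continue;
            int k0 = std::max(0, -dz), k1 = std::min(nz, nz - dz);
            int j0 = std::max(0, -dy), j1 = std::min(ny, ny - dy);
            int i0 = std::max(0, -dx), i1 = std::min(nx, nx - dx);
            for (int k = k0; k < k1; ++k)
              for (int j = j0; j < j1; ++j) {
                R_xlen_t po = idx3(i0, j, k, nx, ny);
                R_xlen_t pi = idx3(i0 + dx, j + dy, k + dz, nx, ny);
                for (int i = i0; i < i1; ++i, ++po, ++pi)
                  yp[po] += wv * xc[pi];
              }
          }
    }
  }
  y.attr("dim") = IntegerVector::create(nx, ny, nz, co);
  return y;
}

// Backward pass: returns grads w.r.t. input, weights, bias.
// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, IntegerVector dim, int ci,
                    NumericVector w, int co, NumericVector gy) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t vol = (R_xlen_t)nx * ny * nz;
  NumericVector gx(vol * ci), gw(w.size()), gb(co);
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* gyp = gy.begin();
  for (int oc = 0; oc < co; ++oc) {
    const double* gc = gyp + vol * oc;
    double acc = 0;
    for (R_xlen_t p = 0; p < vol; ++p) acc += gc[p];
    gb[oc] = acc;
    for (int icc = 0; icc < ci; ++icc) {
      const double* xc = xp + vol * icc;
      double* gxc = gx.begin() + vol * icc;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            R_xlen_t wi = (dx + 1) + 3 * ((dy + 1) + 3 * ((dz + 1) + 3 * ((R_xlen_t)icc + (R_xlen_t)ci * oc)));
            double wv = wp[wi];
            double gwacc = 0;
            int k0 = std::max(0, -dz), k1 = std::min(nz, nz - dz);
            int j0 = std::max(0, -dy), j1 = std::min(ny, ny - dy);
            int i0 = std::max(0, -dx), i1 = std::min(nx, nx - dx);
            for (int k = k0; k < k1; ++k)
              for (int j = j0; j < j1; ++j) {
                R_xlen_t po = idx3(i0, j, k, nx, ny);
                R_xlen_t pi = idx3(i0 + dx, j + dy, k + dz, nx, ny);
                for (int i = i0; i < i1; ++i, ++po, ++pi) {
                  double g = gc[po];
                  gwacc += g * xc[pi];
                  gxc[pi] += g * wv;
                }
              }
            gw[wi] += gwacc;
          }
    }
  }
  gx.attr("dim") = IntegerVector::create(nx, ny, nz, ci);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x average pooling over the three spatial axes of [nx,ny,nz,c].
// [[Rcpp::export]]
NumericVector cpp_avgpool2(NumericVector x, IntegerVector dim, int nc) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int mx = nx / 2, my = ny / 2, mz = nz / 2;
  R_xlen_t voli = (R_xlen_t)nx * ny * nz, volo = (R_xlen_t)mx * my * mz;
  NumericVector y(volo * nc);
  for (int c = 0; c < nc; ++c) {
    const double* xc = x.begin() + voli * c;
    double* yc = y.begin() + volo * c;
    for (int k = 0; k < mz; ++k)
      for (int j = 0; j < my; ++j)
        for (int i = 0; i < mx; ++i) {
          double s = 0;
          for (int dk = 0; dk < 2; ++dk)
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di)
                s += xc[idx3(2 * i + di, 2 * j + dj, 2 * k + dk, nx, ny)];
          yc[idx3(i, j, k, mx, my)] = s / 8.0;
        }
  }
  y.attr("dim") = IntegerVector::create(mx, my, mz, nc);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool2_bwd(NumericVector gy, IntegerVector outdim, int nc) {
  int nx = outdim[0], ny = outdim[1], nz = outdim[2];
  int mx = nx / 2, my = ny / 2, mz = nz / 2;
  R_xlen_t voli = (R_xlen_t)nx * ny * nz, volo = (R_xlen_t)mx * my * mz;
  NumericVector gx(voli * nc);
  for (int c = 0; c < nc; ++c) {
    const double* gc = gy.begin() + volo * c;
    double* xc = gx.begin() + voli * c;
    for (int k = 0; k < mz; ++k)
      for (int j = 0; j < my; ++j)
        for (int i = 0; i < mx; ++i) {
          double g = gc[idx3(i, j, k, mx, my)] / 8.0;
          for (int dk = 0; dk < 2; ++dk)
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di)
                xc[idx3(2 * i + di, 2 * j + dj, 2 * k + dk, nx, ny)] = g;
        }
  }
  gx.attr("dim") = IntegerVector::create(nx, ny, nz, nc);
  return gx;
}

// Nearest-neighbour 2x upsampling of [mx,my,mz,c] to [2mx,2my,2mz,c].
// [[Rcpp::export]]
NumericVector cpp_upsample2(NumericVector x, IntegerVector dim, int nc) {
  int mx = dim[0], my = dim[1], mz = dim[2];
  int nx = 2 * mx, ny = 2 * my, nz = 2 * mz;
  R_xlen_t voli = (R_xlen_t)mx * my * mz, volo = (R_xlen_t)nx * ny * nz;
  NumericVector y(volo * nc);
  for (int c = 0; c < nc; ++c) {
    const double* xc = x.begin() + voli * c;
    double* yc = y.begin() + volo * c;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i)
          yc[idx3(i, j, k, nx, ny)] = xc[idx3(i / 2, j / 2, k / 2, mx, my)];
  }
  y.attr("dim") = IntegerVector::create(nx, ny, nz, nc);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bwd(NumericVector gy, IntegerVector outdim, int nc) {
  int nx = outdim[0], ny = outdim[1], nz = outdim[2];
  int mx = nx / 2, my = ny / 2, mz = nz / 2;
  R_xlen_t voli = (R_xlen_t)mx * my * mz, volo = (R_xlen_t)nx * ny * nz;
  NumericVector gx(voli * nc);
  for (int c = 0; c < nc; ++c) {
    const double* gc = gy.begin() + volo * c;
    double* xc = gx.begin() + voli * c;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i)
          xc[idx3(i / 2, j / 2, k / 2, mx, my)] += gc[idx3(i, j, k, nx, ny)];
  }
  gx.attr("dim") = IntegerVector::create(mx, my, mz, nc);
  return gx;
}
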