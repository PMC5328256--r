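// Voxel-level kernels: trilinear interpolation, exact Euclidean distance
// transform, separable Gaussian smoothing, cubic B-spline transform
// evaluation, registration cost/gradient, connected components.
// All physical coordinates are in mm; voxel (i,j,k) sits at
// origin + (i,j,k) * spacing with 0-based indices.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
#include <stack>
using namespace Rcpp;

static inline int clampi(int x, int lo, int hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Trilinear interpolation at one continuous voxel coordinate (cx,cy,cz).
// Corners outside the grid contribute `fill`.
static double trilin(const double* v, int d1, int d2, int d3,
                     double cx, double cy, double cz, double fill) {
  int i0 = (int)std::floor(cx), j0 = (int)std::floor(cy), k0 = (int)std::floor(cz);
  double fx = cx - i0, fy = cy - j0, fz = cz - k0;
  double out = 0.0;
  for (int dk = 0; dk < 2; ++dk) {
    int k = k0 + dk;
    double wz = dk ? fz : 1.0 - fz;
    if (wz == 0.0) continue;
    for (int dj = 0; dj < 2; ++dj) {
      int j = j0 + dj;
      double wy = dj ? fy : 1.0 - fy;
      if (wy == 0.0) continue;
      for (int di = 0; di < 2; ++di) {
        int i = i0 + di;
        double wx = di ? fx : 1.0 - fx;
        if (wx == 0.0) continue;
        double val;
        if (i < 0 || j < 0 || k < 0 || i >= d1 || j >= d2 || k >= d3)
          val = fill;
        else
          val = v[i + (size_t)d1 * (j + (size_t)d2 * k)];
        out += wx * wy * wz * val;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_interp(NumericVector vol, IntegerVector dim,
                         NumericVector spacing, NumericVector origin,
                         NumericMatrix pts, double fill, int mode) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  int n = pts.nrow();
  NumericVector out(n);
  const double* v = vol.begin();
  for (int p = 0; p < n; ++p) {
    double cx = (pts(p, 0) - origin[0]) / spacing[0];
    double cy = (pts(p, 1) - origin[1]) / spacing[1];
    double cz = (pts(p, 2) - origin[2]) / spacing[2];
    if (mode == 0) { // nearest
      int i = (int)std::lround(cx), j = (int)std::lround(cy), k = (int)std::lround(cz);
      if (i < 0 || j < 0 || k < 0 || i >= d1 || j >= d2 || k >= d3)
        out[p] = fill;
      else
        out[p] = v[i + (size_t)d1 * (j + (size_t)d2 * k)];
    } else {
      out[p] = trilin(v, d1, d2, d3, cx, cy, cz, fill);
    }
  }
  return out;
}

// ---- Exact Euclidean distance transform (Felzenszwalb & Huttenlocher),
// ---- anisotropic spacing supported by running the 1D transform on
// ---- physical sample positions x_i = i * h.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 double h, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double xq = q * h, s;
    while (true) {
      double xv = v[k] * h;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * (xq - xv));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * h;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * h;
    d[q] = dx * dx + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt(IntegerVector mask, IntegerVector dim,
                      NumericVector spacing) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  size_t n = (size_t)d1 * d2 * d3;
  const double INF = 1e30;
  std::vector<double> g(n);
  for (size_t i = 0; i < n; ++i) g[i] = mask[i] ? 0.0 : INF;

  // pass along axis 1
  {
    std::vector<double> f(d1), d(d1);
    for (int k = 0; k < d3; ++k)
      for (int j = 0; j < d2; ++j) {
        size_t base = (size_t)d1 * (j + (size_t)d2 * k);
        for (int i = 0; i < d1; ++i) f[i] = g[base + i];
        dt1d(f, d, spacing[0], d1);
        for (int i = 0; i < d1; ++i) g[base + i] = d[i];
      }
  }
  // axis 2
  {
    std::vector<double> f(d2), d(d2);
    for (int k = 0; k < d3; ++k)
      for (int i = 0; i < d1; ++i) {
        for (int j = 0; j < d2; ++j) f[j] = g[i + (size_t)d1 * (j + (size_t)d2 * k)];
        dt1d(f, d, spacing[1], d2);
        for (int j = 0; j < d2; ++j) g[i + (size_t)d1 * (j + (size_t)d2 * k)] = d[j];
      }
  }
  // axis 3
  {
    std::vector<double> f(d3), d(d3);
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        for (int k = 0; k < d3; ++k) f[k] = g[i + (size_t)d1 * (j + (size_t)d2 * k)];
        dt1d(f, d, spacing[2], d3);
        for (int k = 0; k < d3; ++k) g[i + (size_t)d1 * (j + (size_t)d2 * k)] = d[k];
      }
  }
  NumericVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = std::sqrt(g[i]);
  return out;
}

// ---- Separable Gaussian smoothing, reflected boundaries, sigma in voxels.
static void smooth_axis(std::vector<double>& v, int d1, int d2, int d3,
                        int axis, double sigma) {
  if (sigma <= 0) return;
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> kern(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    kern[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += kern[i + r];
  }
  for (double& k : kern) k /= s;
  int len = axis == 0 ? d1 : (axis == 1 ? d2 : d3);
  std::vector<double> line(len), out(len);
  int n1 = axis == 0 ? d2 : d1;
  int n2 = axis == 2 ? d2 : d3;
  for (int b = 0; b < n2; ++b)
    for (int a = 0; a < n1; ++a) {
      for (int q = 0; q < len; ++q) {
        size_t idx;
        if (axis == 0) idx = q + (size_t)d1 * (a + (size_t)d2 * b);
        else if (axis == 1) idx = a + (size_t)d1 * (q + (size_t)d2 * b);
        else idx = a + (size_t)d1 * (b + (size_t)d2 * q);
        line[q] = v[idx];
      }
      for (int q = 0; q < len; ++q) {
        double acc = 0;
        for (int i = -r; i <= r; ++i) {
          int qq = q + i;
          if (qq < 0) qq = -qq - 1;           // reflect
          if (qq >= len) qq = 2 * len - qq - 1;
          qq = clampi(qq, 0, len - 1);
          acc += kern[i + r] * line[qq];
        }
        out[q] = acc;
      }
      for (int q = 0; q < len; ++q) {
        size_t idx;
        if (axis == 0) idx = q + (size_t)d1 * (a + (size_t)d2 * b);
        else if (axis == 1) idx = a + (size_t)d1 * (q + (size_t)d2 * b);
        else idx = a + (size_t)d1 * (b + (size_t)d2 * q);
        v[idx] = out[q];
      }
    }
}

// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector vol, IntegerVector dim,
                               NumericVector sigma) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  std::vector<double> v(vol.begin(), vol.end());
  smooth_axis(v, d1, d2, d3, 0, sigma[0]);
  smooth_axis(v, d1, d2, d3, 1, sigma[1]);
  smooth_axis(v, d1, d2, d3, 2, sigma[2]);
  return NumericVector(v.begin(), v.end());
}

// ---- Connected components, 6-connectivity.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dim) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  size_t n = (size_t)d1 * d2 * d3;
  IntegerVector lab(n, 0);
  int cur = 0;
  std::stack<size_t> st;
  const int off1[6] = {-1, 1, 0, 0, 0, 0};
  const int off2[6] = {0, 0, -1, 1, 0, 0};
  const int off3[6] = {0, 0, 0, 0, -1, 1};
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    lab[s] = cur;
    st.push(s);
    while (!st.empty()) {
      size_t p = st.top(); st.pop();
      int k = p / ((size_t)d1 * d2);
      int rem = p - (size_t)k * d1 * d2;
      int j = rem / d1;
      int i = rem - j * d1;
      for (int m = 0; m < 6; ++m) {
        int ii = i + off1[m], jj = j + off2[m], kk = k + off3[m];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= d1 || jj >= d2 || kk >= d3) continue;
        size_t q = ii + (size_t)d1 * (jj + (size_t)d2 * kk);
        if (mask[q] && !lab[q]) { lab[q] = cur; st.push(q); }
      }
    }
  }
  return lab;
}

// ---- Cubic B-spline basis (centered, support (-2,2)).
static inline double bspl3(double s) {
  s = std::fabs(s);
  if (s < 1.0) return (4.0 - 6.0 * s * s + 3.0 * s * s * s) / 6.0;
  if (s < 2.0) { double t = 2.0 - s; return t * t * t / 6.0; }
  return 0.0;
}

// Evaluate B-spline displacement u(x) at points.  Coefficient layout:
// coef[cp + ncp * comp] with cp = i + n1*(j + n2*k) (0-based), comp 0..2.
// Control point (i,j,k) sits at gorg + (i,j,k)*gsp.  Indices are clamped,
// i.e. the outermost coefficients extend beyond the grid edge.
// [[Rcpp::export]]
NumericMatrix cpp_bspline_eval(NumericVector coef, IntegerVector gdim,
                               NumericVector gorg, NumericVector gsp,
                               NumericMatrix pts) {
  int n1 = gdim[0], n2 = gdim[1], n3 = gdim[2];
  size_t ncp = (size_t)n1 * n2 * n3;
  int n = pts.nrow();
  NumericMatrix out(n, 3);
  for (int p = 0; p < n; ++p) {
    double g1 = (pts(p, 0) - gorg[0]) / gsp[0];
    double g2 = (pts(p, 1) - gorg[1]) / gsp[1];
    double g3 = (pts(p, 2) - gorg[2]) / gsp[2];
    int i0 = (int)std::floor(g1), j0 = (int)std::floor(g2), k0 = (int)std::floor(g3);
    double u0 = 0, u1 = 0, u2 = 0;
    for (int dk = -1; dk <= 2; ++dk) {
      int k = clampi(k0 + dk, 0, n3 - 1);
      double wz = bspl3(g3 - (k0 + dk));
      if (wz == 0) continue;
      for (int dj = -1; dj <= 2; ++dj) {
        int j = clampi(j0 + dj, 0, n2 - 1);
        double wy = bspl3(g2 - (j0 + dj));
        if (wy == 0) continue;
        double wyz = wy * wz;
        for (int di = -1; di <= 2; ++di) {
          int i = clampi(i0 + di, 0, n1 - 1);
          double w = bspl3(g1 - (i0 + di)) * wyz;
          if (w == 0) continue;
          size_t cp = i + (size_t)n1 * (j + (size_t)n2 * k);
          u0 += w * coef[cp];
          u1 += w * coef[cp + ncp];
          u2 += w * coef[cp + 2 * ncp];
        }
      }
    }
    out(p, 0) = u0; out(p, 1) = u1; out(p, 2) = u2;
  }
  return out;
}

// ---- Central-difference gradient volumes (mm^-1 units).
// [[Rcpp::export]]
List cpp_gradient(NumericVector vol, IntegerVector dim, NumericVector spacing) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  size_t n = (size_t)d1 * d2 * d3;
  NumericVector gx(n), gy(n), gz(n);
  const double* v = vol.begin();
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        size_t p = i + (size_t)d1 * (j + (size_t)d2 * k);
        int ip = clampi(i + 1, 0, d1 - 1), im = clampi(i - 1, 0, d1 - 1);
        int jp = clampi(j + 1, 0, d2 - 1), jm = clampi(j - 1, 0, d2 - 1);
        int kp = clampi(k + 1, 0, d3 - 1), km = clampi(k - 1, 0, d3 - 1);
        gx[p] = (v[ip + (size_t)d1 * (j + (size_t)d2 * k)] -
                 v[im + (size_t)d1 * (j + (size_t)d2 * k)]) / ((ip - im) * spacing[0]);
        gy[p] = (v[i + (size_t)d1 * (jp + (size_t)d2 * k)] -
                 v[i + (size_t)d1 * (jm + (size_t)d2 * k)]) / ((jp - jm) * spacing[1]);
        gz[p] = (v[i + (size_t)d1 * (j + (size_t)d2 * kp)] -
                 v[i + (size_t)d1 * (j + (size_t)d2 * km)]) / ((kp - km) * spacing[2]);
      }
  return List::create(gx, gy, gz);
}

// ---- Registration cost + gradient.
//
// Total transform: T(x) = M * inner(x) + o, with
//   inner(x) = A (x - c) + c + b                  (kind = 0, par = [A row-major, b])
//   inner(x) = x + u(x)  (cubic B-spline)         (kind = 1, par = coef layout above)
// SSD terms share the sampled fixed points; each has its own fixed values and
// moving volume (+ precomputed gradient).  LM terms are (fixed, moving) point
// matrices.  Cost C = sum_i w_i S_i / sum_i w_i.
// [[Rcpp::export]]
List cpp_reg_cost_grad(int kind, NumericVector par,
                       NumericMatrix preM, NumericVector preo,
                       NumericVector center,
                       IntegerVector gdim, NumericVector gorg, NumericVector gsp,
                       NumericMatrix pts, NumericMatrix fixvals,
                       List movvols, NumericVector ssd_w,
                       List lm_fix, List lm_mov, NumericVector lm_w,
                       bool want_grad) {
  int npts = pts.nrow();
  int nssd = fixvals.ncol();
  int nlm = lm_w.size();
  double wsum = 0;
  for (int i = 0; i < nssd; ++i) wsum += ssd_w[i];
  for (int i = 0; i < nlm; ++i) wsum += lm_w[i];

  int npar = par.size();
  NumericVector grad(want_grad ? npar : 0);
  NumericVector term_costs(nssd + nlm);

  int n1 = 0, n2 = 0, n3 = 0;
  size_t ncp = 0;
  if (kind == 1) { n1 = gdim[0]; n2 = gdim[1]; n3 = gdim[2]; ncp = (size_t)n1 * n2 * n3; }

  // scratch for B-spline weights at one point
  int widx[64];
  double wval[64];

  // Apply transform to a point; optionally record B-spline weights.
  auto apply_pt = [&](double x, double y, double z,
                      double& tx, double& ty, double& tz, int& nw) {
    double ix, iy, iz;
    if (kind == 0) {
      double dx = x - center[0], dy = y - center[1], dz = z - center[2];
      ix = par[0] * dx + par[1] * dy + par[2] * dz + center[0] + par[9];
      iy = par[3] * dx + par[4] * dy + par[5] * dz + center[1] + par[10];
      iz = par[6] * dx + par[7] * dy + par[8] * dz + center[2] + par[11];
      nw = 0;
    } else {
      double g1 = (x - gorg[0]) / gsp[0];
      double g2 = (y - gorg[1]) / gsp[1];
      double g3 = (z - gorg[2]) / gsp[2];
      int i0 = (int)std::floor(g1), j0 = (int)std::floor(g2), k0 = (int)std::floor(g3);
      double u0 = 0, u1 = 0, u2 = 0;
      nw = 0;
      for (int dk = -1; dk <= 2; ++dk) {
        int k = clampi(k0 + dk, 0, n3 - 1);
        double wz = bspl3(g3 - (k0 + dk));
        if (wz == 0) continue;
        for (int dj = -1; dj <= 2; ++dj) {
          int j = clampi(j0 + dj, 0, n2 - 1);
          double wy = bspl3(g2 - (j0 + dj)) * wz;
          if (wy == 0) continue;
          for (int di = -1; di <= 2; ++di) {
            int i = clampi(i0 + di, 0, n1 - 1);
            double w = bspl3(g1 - (i0 + di)) * wy;
            if (w == 0) continue;
            size_t cp = i + (size_t)n1 * (j + (size_t)n2 * k);
            u0 += w * par[cp];
            u1 += w * par[cp + ncp];
            u2 += w * par[cp + 2 * ncp];
            widx[nw] = cp; wval[nw] = w; ++nw;
          }
        }
      }
      ix = x + u0; iy = y + u1; iz = z + u2;
    }
    tx = preM(0, 0) * ix + preM(0, 1) * iy + preM(0, 2) * iz + preo[0];
    ty = preM(1, 0) * ix + preM(1, 1) * iy + preM(1, 2) * iz + preo[1];
    tz = preM(2, 0) * ix + preM(2, 1) * iy + preM(2, 2) * iz + preo[2];
  };

  // Accumulate gradient for one point given dC/dT (chain through preM).
  auto accum = [&](double x, double y, double z,
                   double dTx, double dTy, double dTz, int nw) {
    // d/d(inner) = preM^T * dT
    double ax = preM(0, 0) * dTx + preM(1, 0) * dTy + preM(2, 0) * dTz;
    double ay = preM(0, 1) * dTx + preM(1, 1) * dTy + preM(2, 1) * dTz;
    double az = preM(0, 2) * dTx + preM(1, 2) * dTy + preM(2, 2) * dTz;
    if (kind == 0) {
      double dx = x - center[0], dy = y - center[1], dz = z - center[2];
      grad[0] += ax * dx; grad[1] += ax * dy; grad[2] += ax * dz;
      grad[3] += ay * dx; grad[4] += ay * dy; grad[5] += ay * dz;
      grad[6] += az * dx; grad[7] += az * dy; grad[8] += az * dz;
      grad[9] += ax; grad[10] += ay; grad[11] += az;
    } else {
      for (int m = 0; m < nw; ++m) {
        grad[widx[m]] += wval[m] * ax;
        grad[widx[m] + ncp] += wval[m] * ay;
        grad[widx[m] + 2 * ncp] += wval[m] * az;
      }
    }
  };

  // --- SSD terms ---
  if (nssd > 0) {
    // unpack moving volumes
    std::vector<const double*> mv(nssd), mgx(nssd), mgy(nssd), mgz(nssd);
    std::vector<IntegerVector> mdim(nssd);
    std::vector<NumericVector> msp(nssd), morg(nssd);
    std::vector<double> fills(nssd);
    for (int t = 0; t < nssd; ++t) {
      List mvl = movvols[t];
      NumericVector vv = mvl["vol"];
      mv[t] = vv.begin();
      mdim[t] = as<IntegerVector>(mvl["dim"]);
      msp[t] = as<NumericVector>(mvl["spacing"]);
      morg[t] = as<NumericVector>(mvl["origin"]);
      fills[t] = as<double>(mvl["fill"]);
      NumericVector g1 = mvl["gx"], g2 = mvl["gy"], g3 = mvl["gz"];
      mgx[t] = g1.begin(); mgy[t] = g2.begin(); mgz[t] = g3.begin();
    }
    std::vector<double> acc(nssd, 0.0);
    for (int p = 0; p < npts; ++p) {
      double tx, ty, tz; int nw;
      apply_pt(pts(p, 0), pts(p, 1), pts(p, 2), tx, ty, tz, nw);
      double dTx = 0, dTy = 0, dTz = 0;
      bool any = false;
      for (int t = 0; t < nssd; ++t) {
        double cx = (tx - morg[t][0]) / msp[t][0];
        double cy = (ty - morg[t][1]) / msp[t][1];
        double cz = (tz - morg[t][2]) / msp[t][2];
        int D1 = mdim[t][0], D2 = mdim[t][1], D3 = mdim[t][2];
        double mval = trilin(mv[t], D1, D2, D3, cx, cy, cz, fills[t]);
        double e = mval - fixvals(p, t);
        acc[t] += e * e;
        if (want_grad) {
          double gx = trilin(mgx[t], D1, D2, D3, cx, cy, cz, 0.0);
          double gy = trilin(mgy[t], D1, D2, D3, cx, cy, cz, 0.0);
          double gz = trilin(mgz[t], D1, D2, D3, cx, cy, cz, 0.0);
          double f = 2.0 * ssd_w[t] / (npts * wsum);
          dTx += f * e * gx; dTy += f * e * gy; dTz += f * e * gz;
          any = true;
        }
      }
      if (any) accum(pts(p, 0), pts(p, 1), pts(p, 2), dTx, dTy, dTz, nw);
    }
    for (int t = 0; t < nssd; ++t) term_costs[t] = acc[t] / npts;
  }

  // --- LM terms ---
  for (int t = 0; t < nlm; ++t) {
    NumericMatrix fx = lm_fix[t], mvp = lm_mov[t];
    int P = fx.nrow();
    double acc = 0;
    for (int p = 0; p < P; ++p) {
      double tx, ty, tz; int nw;
      apply_pt(fx(p, 0), fx(p, 1), fx(p, 2), tx, ty, tz, nw);
      double rx = tx - mvp(p, 0), ry = ty - mvp(p, 1), rz = tz - mvp(p, 2);
      double nrm = std::sqrt(rx * rx + ry * ry + rz * rz);
      acc += nrm;
      if (want_grad && nrm > 1e-12) {
        double f = lm_w[t] / (P * wsum * nrm);
        accum(fx(p, 0), fx(p, 1), fx(p, 2), f * rx, f * ry, f * rz, nw);
      }
    }
    term_costs[nssd + t] = acc / P;
  }

  double cost = 0;
  for (int t = 0; t < nssd; ++t) cost += ssd_w[t] * term_costs[t];
  for (int t = 0; t < nlm; ++t) cost += lm_w[t] * term_costs[nssd + t];
  cost /= wsum;

  return List::create(_["cost"] = cost, _["terms"] = term_costs,
                      _["grad"] = grad);
}
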