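#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// Chord length of the segment p0 -> p1 inside an axis-aligned ellipsoid.
// Quadratic in the segment parameter s in [0, 1]; tangent or missing rays
// give zero length.
static double ellipsoidChord(const double *p0, const double *p1,
                             const double *c, const double *a) {
  double u[3], w[3];
  double A = 0.0, B = 0.0, C = -1.0, L2 = 0.0;
  for (int k = 0; k < 3; ++k) {
    u[k] = p1[k] - p0[k];
    w[k] = p0[k] - c[k];
    double ia2 = 1.0 / (a[k] * a[k]);
    A += u[k] * u[k] * ia2;
    B += 2.0 * u[k] * w[k] * ia2;
    C += w[k] * w[k] * ia2;
    L2 += u[k] * u[k];
  }
  if (A <= 0.0) return 0.0;
  double disc = B * B - 4.0 * A * C;
  if (disc <= 0.0) return 0.0;
  double sq = std::sqrt(disc);
  double s1 = (-B - sq) / (2.0 * A);
  double s2 = (-B + sq) / (2.0 * A);
  double lo = s1 > 0.0 ? s1 : 0.0;
  double hi = s2 < 1.0 ? s2 : 1.0;
  if (hi <= lo) return 0.0;
  return (hi - lo) * std::sqrt(L2);
}

// Straight-ray time of flight through a two-speed medium. When the inner
// speed equals the background (or there is no ellipsoid) the homogeneous
// expression dist/bg is returned directly so the two paths agree bit for
// bit.
static double tofRay(const double *det, const double *vox, double bg,
                     bool hasEll, const double *ec, const double *ea,
                     double inner) {
  double dx = vox[0] - det[0], dy = vox[1] - det[1], dz = vox[2] - det[2];
  double dist = std::sqrt(dx * dx + dy * dy + dz * dz);
  if (!hasEll || inner == bg) return dist / bg;
  double lin = ellipsoidChord(det, vox, ec, ea);
  if (lin <= 0.0) return dist / bg;
  return lin / inner + (dist - lin) / bg;
}

// [[Rcpp::export(name = ".cppTimeOfFlight")]]
NumericVector cppTimeOfFlight(NumericMatrix det, NumericMatrix vox,
                              double bg, bool hasEll, NumericVector ec,
                              NumericVector ea, double inner) {
  int n = det.nrow();
  NumericVector out(n);
  double c_[3] = {0, 0, 0}, a_[3] = {1, 1, 1};
  if (hasEll)
    for (int k = 0; k < 3; ++k) { c_[k] = ec[k]; a_[k] = ea[k]; }
  for (int i = 0; i < n; ++i) {
    double d[3] = {det(i, 0), det(i, 1), det(i, 2)};
    double v[3] = {vox(i, 0), vox(i, 1), vox(i, 2)};
    out[i] = tofRay(d, v, bg, hasEll, c_, a_, inner);
  }
  return out;
}

// Forward projection: sum of uniformly heated sphere N-waves over all
// absorbers, per detector, sampled either pointwise or as the exact
// average over each sample bin (closed-form antiderivative), with a
// frequency-independent directivity gain per incidence angle.
// dirTable holds gains at angles 0..90 deg at step dirStep.
// [[Rcpp::export(name = ".cppForwardProject")]]
NumericMatrix cppForwardProject(NumericMatrix centers, NumericVector radii,
                                NumericVector amps, NumericMatrix det,
                                NumericVector dirTable, double dirStep,
                                double sos, double fs, double t0, int nt,
                                bool binAverage) {
  int nAbs = centers.nrow(), nDet = det.nrow();
  NumericMatrix out(nDet, nt);
  double dt = 1.0 / fs;
  int nDir = dirTable.size();
  for (int m = 0; m < nDet; ++m) {
    double dxm = det(m, 0), dym = det(m, 1), dzm = det(m, 2);
    double *row = &out(m, 0); // column-major: rows are strided
    (void)row;
    for (int s = 0; s < nAbs; ++s) {
      double dx = centers(s, 0) - dxm;
      double dy = centers(s, 1) - dym;
      double dz = centers(s, 2) - dzm;
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      double a = radii[s];
      if (d <= a) stop("detector lies inside an absorber sphere");
      double A = amps[s];
      if (A == 0.0) continue;
      // incidence angle from the detector normal (+z)
      double cosTh = std::fabs(dz) / d;
      if (cosTh > 1.0) cosTh = 1.0;
      double ang = std::acos(cosTh) * 180.0 / M_PI;
      double fi = ang / dirStep;
      int i0 = (int)fi;
      if (i0 >= nDir - 1) i0 = nDir - 2;
      double fr = fi - i0;
      double gain = dirTable[i0] * (1.0 - fr) + dirTable[i0 + 1] * fr;
      if (gain <= 0.0) continue;
      double Ag = A * gain;
      double t1 = (d - a) / sos, t2 = (d + a) / sos;
      if (binAverage) {
        // F(t) = integral of p from t1 to clamp(t); zero at both ends
        int k0 = (int)std::floor((t1 - dt / 2 - t0) / dt);
        int k1 = (int)std::ceil((t2 + dt / 2 - t0) / dt);
        if (k0 < 0) k0 = 0;
        if (k1 > nt - 1) k1 = nt - 1;
        double prevF = 0.0;
        bool first = true;
        for (int k = k0; k <= k1; ++k) {
          double tb = t0 + k * dt + dt / 2; // right edge of bin k
          double tc = tb < t1 ? t1 : (tb > t2 ? t2 : tb);
          double F = (Ag / (2.0 * d)) *
                     (d * (tc - t1) - 0.5 * sos * (tc * tc - t1 * t1));
          if (first) {
            // integral over the partial first bin
            double ta = tb - dt;
            double tca = ta < t1 ? t1 : (ta > t2 ? t2 : ta);
            prevF = (Ag / (2.0 * d)) *
                    (d * (tca - t1) - 0.5 * sos * (tca * tca - t1 * t1));
            first = false;
          }
          out(m, k) += (F - prevF) / dt;
          prevF = F;
        }
      } else {
        int k0 = (int)std::ceil((t1 - t0) * fs);
        int k1 = (int)std::floor((t2 - t0) * fs);
        if (k0 < 0) k0 = 0;
        if (k1 > nt - 1) k1 = nt - 1;
        for (int k = k0; k <= k1; ++k) {
          double t = t0 + k * dt;
          if (std::fabs(d - sos * t) < a)
            out(m, k) += Ag * (d - sos * t) / (2.0 * d);
        }
      }
    }
  }
  return out;
}

// Universal back projection: for each voxel, sum the filtered term
// b(t) = 2 p(t) - 2 t dp/dt (precomputed by the caller) at the analytic
// time of flight, weighted by the solid angle cos(theta) * pitch^2 / dist^2
// subtended by each detector cell, normalised by the total weight over the
// aperture. Out-of-record samples contribute zero and are counted.
// [[Rcpp::export(name = ".cppUbp")]]
List cppUbp(NumericMatrix b, NumericMatrix det, double pitch, double fs,
            double t0, NumericVector gOrigin, double voxel,
            IntegerVector shape, double bg, bool hasEll, NumericVector ec,
            NumericVector ea, double inner) {
  int nDet = det.nrow(), nt = b.ncol();
  int nx = shape[0], ny = shape[1], nz = shape[2];
  NumericVector vals((R_xlen_t)nx * ny * nz);
  double c_[3] = {0, 0, 0}, a_[3] = {1, 1, 1};
  if (hasEll)
    for (int k = 0; k < 3; ++k) { c_[k] = ec[k]; a_[k] = ea[k]; }
  double truncated = 0.0, pairs = 0.0;
  R_xlen_t idx = 0;
  for (int iz = 0; iz < nz; ++iz) {
    double vz = gOrigin[2] + iz * voxel;
    for (int iy = 0; iy < ny; ++iy) {
      double vy = gOrigin[1] + iy * voxel;
      for (int ix = 0; ix < nx; ++ix) {
        double vx = gOrigin[0] + ix * voxel;
        double vox[3] = {vx, vy, vz};
        double num = 0.0, den = 0.0;
        for (int m = 0; m < nDet; ++m) {
          double d0[3] = {det(m, 0), det(m, 1), det(m, 2)};
          double dx = vx - d0[0], dy = vy - d0[1], dz = vz - d0[2];
          double dist = std::sqrt(dx * dx + dy * dy + dz * dz);
          if (dist < voxel * 0.5) continue; // voxel at the detector
          double w = std::fabs(dz) / dist * pitch * pitch / (dist * dist);
          double tof = tofRay(d0, vox, bg, hasEll, c_, a_, inner);
          double k = (tof - t0) * fs;
          pairs += 1.0;
          den += w;
          if (k < 0.0 || k > nt - 2.0) { truncated += 1.0; continue; }
          int k0 = (int)k;
          double fr = k - k0;
          num += w * (b(m, k0) * (1.0 - fr) + b(m, k0 + 1) * fr);
        }
        // note: R arrays are [ix, iy, iz] column-major
        vals[(R_xlen_t)ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)] =
            den > 0.0 ? num / den : 0.0;
        ++idx;
      }
    }
  }
  (void)idx;
  return List::create(_["values"] = vals,
                      _["truncFrac"] = pairs > 0 ? truncated / pairs : 0.0);
}

// Hysteresis labelling with 26-connectivity: components of the >= low mask
// that contain at least one >= high seed. Returns 0 background, 1..K in
// discovery order (caller relabels by size).
// [[Rcpp::export(name = ".cppHysteresisLabel")]]
IntegerVector cppHysteresisLabel(NumericVector vals, IntegerVector shape,
                                 double high, double low) {
  int nx = shape[0], ny = shape[1], nz = shape[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  std::vector<char> inMask(n);
  for (R_xlen_t i = 0; i < n; ++i) inMask[i] = vals[i] >= low;
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (vals[i] < high || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    q.push(i);
    while (!q.empty()) {
      R_xlen_t cur = q.front(); q.pop();
      int cx = cur % nx, cy = (cur / nx) % ny, cz = cur / ((R_xlen_t)nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int x = cx + dx, y = cy + dy, z = cz + dz;
            if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz)
              continue;
            R_xlen_t j = (R_xlen_t)x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
            if (inMask[j] && lab[j] == 0) { lab[j] = next; q.push(j); }
          }
    }
  }
  return lab;
}
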