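#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear interpolation of a 0/1 grid at continuous 0-based index
// coordinates. Nodes outside the grid contribute value 0 (zero padding),
// so the field decays linearly to 0 within one voxel beyond the outermost
// voxel centers and is continuous everywhere.
static inline double trilin(const double* v, int n0, int n1, int n2,
                            double x, double y, double z) {
  if (x <= -1.0 || y <= -1.0 || z <= -1.0 ||
      x >= (double)n0 || y >= (double)n1 || z >= (double)n2)
    return 0.0;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  double fx = x - i0, fy = y - j0, fz = z - k0;
  double acc = 0.0;
  for (int di = 0; di <= 1; ++di) {
    int i = i0 + di;
    if (i < 0 || i >= n0) continue;
    double wx = di ? fx : 1.0 - fx;
    if (wx == 0.0) continue;
    for (int dj = 0; dj <= 1; ++dj) {
      int j = j0 + dj;
      if (j < 0 || j >= n1) continue;
      double wy = dj ? fy : 1.0 - fy;
      if (wy == 0.0) continue;
      for (int dk = 0; dk <= 1; ++dk) {
        int k = k0 + dk;
        if (k < 0 || k >= n2) continue;
        double wz = dk ? fz : 1.0 - fz;
        if (wz == 0.0) continue;
        acc += wx * wy * wz *
               v[(size_t)i + (size_t)n0 * ((size_t)j + (size_t)n1 * (size_t)k)];
      }
    }
  }
  return acc;
}

// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dims,
                            NumericMatrix u) {
  int n0 = dims[0], n1 = dims[1], n2 = dims[2];
  const double* v = vol.begin();
  int n = u.nrow();
  NumericVector out(n);
  for (int r = 0; r < n; ++r)
    out[r] = trilin(v, n0, n1, n2, u(r, 0), u(r, 1), u(r, 2));
  return out;
}

// Cast one expansion vector per surface point along a fixed direction.
//
// u0:   N x 3 starting voxel centers, continuous 0-based index coordinates
// e:    direction in index units per mm of physical arclength
// All positions on the ray are u0 + t * e with t the physical arclength in
// mm; the volume origin never enters the arithmetic, so results are exactly
// invariant under whole-grid translation.
//
// Status codes: 0 accepted, 1 clamped (start outside CTV, length 0),
// 2 rejected (GTV interior re-entry), 3 rejected (barrier crossing),
// 4 failed (GTV exit could not be bracketed within the cap).
// [[Rcpp::export]]
List cpp_cast_rays(NumericVector gtv, NumericVector ctv,
                   Nullable<NumericVector> barrier, IntegerVector dims,
                   NumericMatrix u0, NumericVector e, double stepMm,
                   double capMm, double graceMm, int bisectIter) {
  int n0 = dims[0], n1 = dims[1], n2 = dims[2];
  const double* g = gtv.begin();
  const double* c = ctv.begin();
  NumericVector bkeep = barrier.isNotNull() ? NumericVector(barrier)
                                            : NumericVector(0);
  const double* b = bkeep.size() > 0 ? bkeep.begin() : NULL;

  double e0 = e[0], e1 = e[1], e2 = e[2];
  int n = u0.nrow();
  IntegerVector status(n);
  NumericVector tStart(n), tEnd(n);

  for (int r = 0; r < n; ++r) {
    double x = u0(r, 0), y = u0(r, 1), z = u0(r, 2);
    // --- locate GTV exit crossing ---
    double ts;
    double occ0 = trilin(g, n0, n1, n2, x, y, z);
    if (occ0 < 0.5) {
      ts = 0.0; // degenerate: already outside at the nominal surface point
    } else {
      double lo = 0.0, hi = -1.0;
      for (double t = stepMm; t <= capMm; t += stepMm) {
        double occ = trilin(g, n0, n1, n2, x + t * e0, y + t * e1, z + t * e2);
        if (occ < 0.5) { hi = t; break; }
        lo = t;
      }
      if (hi < 0.0) { // never exits the GTV: grazing/pathological ray
        status[r] = 4; tStart[r] = NA_REAL; tEnd[r] = NA_REAL;
        continue;
      }
      for (int it = 0; it < bisectIter; ++it) {
        double tm = 0.5 * (lo + hi);
        double occ = trilin(g, n0, n1, n2, x + tm * e0, y + tm * e1, z + tm * e2);
        if (occ >= 0.5) lo = tm; else hi = tm;
      }
      ts = 0.5 * (lo + hi);
    }
    tStart[r] = ts;

    // --- clamp: start already outside the CTV ---
    double occC = trilin(c, n0, n1, n2, x + ts * e0, y + ts * e1, z + ts * e2);
    if (occC < 0.5) {
      status[r] = 1; tEnd[r] = ts;
      continue;
    }

    // --- march to the CTV exit, checking re-entry and barrier ---
    int k0i = (int)std::floor(ts / stepMm) + 1;
    double prev = ts; // last point known to be inside the CTV
    int st = -1;
    double te = NA_REAL;
    for (double t = k0i * stepMm; t <= capMm; t += stepMm) {
      double px = x + t * e0, py = y + t * e1, pz = z + t * e2;
      double oc = trilin(c, n0, n1, n2, px, py, pz);
      if (oc < 0.5) { // bracketed the CTV exit in (prev, t]
        double lo = prev, hi = t;
        for (int it = 0; it < bisectIter; ++it) {
          double tm = 0.5 * (lo + hi);
          double o2 = trilin(c, n0, n1, n2, x + tm * e0, y + tm * e1,
                             z + tm * e2);
          if (o2 >= 0.5) lo = tm; else hi = tm;
        }
        te = 0.5 * (lo + hi);
        st = 0;
        break;
      }
      // still inside the CTV: reject on GTV re-entry past the grace zone
      if (t > ts + graceMm) {
        double og = trilin(g, n0, n1, n2, px, py, pz);
        if (og >= 0.5) { st = 2; break; }
      }
      if (b) {
        double ob = trilin(b, n0, n1, n2, px, py, pz);
        if (ob >= 0.5) { st = 3; break; }
      }
      prev = t;
    }
    if (st < 0) st = 4; // CTV exit not found within the cap
    status[r] = st;
    tEnd[r] = te;
  }
  return List::create(_["status"] = status, _["tStart"] = tStart,
                      _["tEnd"] = tEnd);
}
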