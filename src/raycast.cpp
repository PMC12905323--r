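#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exact voxel traversal (Amanatides-Woo) of parallel rays through a binary
// occupancy lattice. Cells visited before the first bone cell on a ray are
// insonified; the first bone cell and every cell behind it (up to the
// imaging depth) are shadowed. Cells reached unblocked by any ray count as
// insonified regardless of other rays being blocked towards them; that
// reconciliation is done by the caller.

// [[Rcpp::export]]
List cast_rays_cpp(NumericMatrix origins, NumericVector dir,
                   NumericVector grid_origin, double res,
                   IntegerVector dims, IntegerVector bone, double depth) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ncell = nx * ny * nz;
  IntegerVector ins(ncell), shadow(ncell);
  double d[3] = {dir[0], dir[1], dir[2]};
  double dn = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
  for (int k = 0; k < 3; ++k) d[k] /= dn;

  for (int r = 0; r < origins.nrow(); ++r) {
    double o[3] = {origins(r,0) - grid_origin[0],
                   origins(r,1) - grid_origin[1],
                   origins(r,2) - grid_origin[2]};
    // clip the ray against the grid box [0, dims*res]
    double t0 = 0.0, t1 = depth;
    bool miss = false;
    for (int k = 0; k < 3; ++k) {
      double lo = 0.0, hi = dims[k] * res;
      if (std::fabs(d[k]) < 1e-12) {
        if (o[k] < lo || o[k] > hi) { miss = true; break; }
      } else {
        double ta = (lo - o[k]) / d[k], tb = (hi - o[k]) / d[k];
        if (ta > tb) std::swap(ta, tb);
        t0 = std::max(t0, ta);
        t1 = std::min(t1, tb);
      }
    }
    if (miss || t0 > t1) continue;

    // entry cell (nudge inside to dodge boundary ties)
    double tcur = t0 + 1e-9;
    int ijk[3];
    bool out = false;
    for (int k = 0; k < 3; ++k) {
      double p = o[k] + tcur * d[k];
      ijk[k] = (int)std::floor(p / res);
      if (ijk[k] < 0) ijk[k] = 0;
      if (ijk[k] >= dims[k]) ijk[k] = dims[k] - 1;
      if (p < -1e-6 || p > dims[k] * res + 1e-6) out = true;
    }
    if (out) continue;

    int step[3]; double tmax[3], tdelta[3];
    for (int k = 0; k < 3; ++k) {
      if (d[k] > 1e-12) {
        step[k] = 1;
        tmax[k] = ((ijk[k] + 1) * res - o[k]) / d[k];
        tdelta[k] = res / d[k];
      } else if (d[k] < -1e-12) {
        step[k] = -1;
        tmax[k] = (ijk[k] * res - o[k]) / d[k];
        tdelta[k] = -res / d[k];
      } else {
        step[k] = 0;
        tmax[k] = R_PosInf;
        tdelta[k] = R_PosInf;
      }
    }

    bool blocked = false;
    while (true) {
      int idx = ijk[0] + nx * (ijk[1] + ny * ijk[2]);
      if (!blocked && bone[idx]) blocked = true;
      if (blocked) shadow[idx] = 1; else ins[idx] = 1;
      // advance to the next cell
      int kmin = 0;
      if (tmax[1] < tmax[kmin]) kmin = 1;
      if (tmax[2] < tmax[kmin]) kmin = 2;
      if (tmax[kmin] > t1) break;
      ijk[kmin] += step[kmin];
      if (ijk[kmin] < 0 || ijk[kmin] >= dims[kmin]) break;
      tmax[kmin] += tdelta[kmin];
    }
  }
  return List::create(_["ins"] = ins, _["shadow"] = shadow);
}
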