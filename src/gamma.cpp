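// Local/global-normalization 3-D gamma index (Low et al. formulation).
// For each reference voxel above the dose cutoff the gamma quadrature is
// minimized over evaluated-dose positions on a sub-voxel lattice within a
// search sphere; candidates are visited in order of increasing distance so
// the search can stop as soon as the spatial term alone exceeds the
// current best gamma^2.
#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

struct Offset {
  double dx, dy, dz, dist2;
};

static inline bool interp3(const double *v, const int *d,
                           const double *sp, const double *orig,
                           double x, double y, double z, double &out) {
  double t1 = (x - orig[0]) / sp[0];
  double t2 = (y - orig[1]) / sp[1];
  double t3 = (z - orig[2]) / sp[2];
  if (t1 < 0 || t1 > d[0] - 1 || t2 < 0 || t2 > d[1] - 1 ||
      t3 < 0 || t3 > d[2] - 1)
    return false;
  int i = std::min((int)t1, d[0] - 2); if (i < 0) i = 0;
  int j = std::min((int)t2, d[1] - 2); if (j < 0) j = 0;
  int k = std::min((int)t3, d[2] - 2); if (k < 0) k = 0;
  double fx = t1 - i, fy = t2 - j, fz = t3 - k;
  long nxy = (long)d[0] * d[1];
#define V(ii, jj, kk) v[(ii) + (long)d[0] * (jj) + nxy * (kk)]
  out =
    V(i, j, k) * (1 - fx) * (1 - fy) * (1 - fz) +
    V(i + 1, j, k) * fx * (1 - fy) * (1 - fz) +
    V(i, j + 1, k) * (1 - fx) * fy * (1 - fz) +
    V(i + 1, j + 1, k) * fx * fy * (1 - fz) +
    V(i, j, k + 1) * (1 - fx) * (1 - fy) * fz +
    V(i + 1, j, k + 1) * fx * (1 - fy) * fz +
    V(i, j + 1, k + 1) * (1 - fx) * fy * fz +
    V(i + 1, j + 1, k + 1) * fx * fy * fz;
#undef V
  return true;
}

// [[Rcpp::export]]
NumericVector gamma_engine_cpp(NumericVector ref, IntegerVector rdim,
                               NumericVector rspacing,
                               NumericVector rorigin,
                               NumericVector ev, IntegerVector edim,
                               NumericVector espacing,
                               NumericVector eorigin,
                               double dose_crit, double dta, bool local,
                               double cutoff_abs, double global_norm,
                               double step, double radius) {
  const int *rd = INTEGER(rdim);
  const double *rs = REAL(rspacing), *ro = REAL(rorigin);
  const int *ed = INTEGER(edim);
  const double *es = REAL(espacing), *eo = REAL(eorigin);
  const double *rv = REAL(ref), *evv = REAL(ev);

  int nstep = (int)std::ceil(radius / step);
  std::vector<Offset> offs;
  offs.reserve((size_t)(2 * nstep + 1) * (2 * nstep + 1));
  for (int a = -nstep; a <= nstep; ++a)
    for (int b = -nstep; b <= nstep; ++b)
      for (int c = -nstep; c <= nstep; ++c) {
        double dx = a * step, dy = b * step, dz = c * step;
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 <= radius * radius + 1e-12)
          offs.push_back({dx, dy, dz, d2});
      }
  std::sort(offs.begin(), offs.end(),
            [](const Offset &a, const Offset &b) {
              return a.dist2 < b.dist2;
            });

  double dta2 = dta * dta;
  long n = (long)rd[0] * rd[1] * rd[2];
  NumericVector out(n, NA_REAL);
  long idx = 0;
  for (int k = 0; k < rd[2]; ++k)
    for (int j = 0; j < rd[1]; ++j)
      for (int i = 0; i < rd[0]; ++i, ++idx) {
        double dr = rv[idx];
        if (!(dr >= cutoff_abs)) continue;  // below cutoff or NaN
        double x = ro[0] + i * rs[0];
        double y = ro[1] + j * rs[1];
        double z = ro[2] + k * rs[2];
        double denom = dose_crit * (local ? dr : global_norm);
        double best = R_PosInf;
        for (const Offset &o : offs) {
          double t2 = o.dist2 / dta2;
          if (t2 >= best) break;
          double de;
          if (!interp3(evv, ed, es, eo, x + o.dx, y + o.dy, z + o.dz, de))
            continue;
          double dd = (de - dr) / denom;
          double g2 = t2 + dd * dd;
          if (g2 < best) best = g2;
        }
        if (R_finite(best)) out[idx] = std::sqrt(best);
      }
  return out;
}
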