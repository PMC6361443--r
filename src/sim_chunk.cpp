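#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Reflect a coordinate into [lo, hi]; clamps pathological overshoots.
static inline double reflect1(double z, double lo, double hi) {
  if (z < lo) z = lo + (lo - z);
  if (z > hi) z = hi - (z - hi);
  if (z < lo) z = lo;
  if (z > hi) z = hi;
  return z;
}

// One simulation chunk of the two-state (rest/active) random-walk cage model.
//
// Per 250 ms tick: a resting mouse switches to active with probability
// p_act[t] (precomputed from the circadian intensity and event gains); an
// active mouse takes a Gaussian random-walk step reflected at the floor
// boundary and reverts to rest with probability p_rest. Electrode e reads
// baseline[e] + sum over mice of coupling[m] * exp(-d^2 / (2 kscale^2))
// + sigma[e] * noise(t, e); every mouse contributes whether resting or
// moving (a resting mouse is a static dielectric load; only movement makes
// first-difference events). Contributions of resting mice are cached and
// only recomputed on movement.
//
// Noise (ticks x electrodes standard normals) and transition uniforms
// (ticks x mice) are drawn vectorized in R and passed in, indexed by tick so
// the draw-to-decision mapping is state-independent (common random numbers
// across scenario variants under a shared seed); random-walk steps are drawn
// from R's RNG here, only for mice that actually move.
// [[Rcpp::export]]
List sim_chunk_cpp(NumericVector p_act, int n_mice,
                   NumericVector x0, NumericVector y0, LogicalVector active0,
                   double p_rest, double step_sd,
                   double xmin, double xmax, double ymin, double ymax,
                   NumericMatrix elec, double kscale,
                   NumericVector coupling, NumericVector baseline,
                   NumericVector sigma, NumericMatrix noise,
                   NumericMatrix trans) {
  const int nt = p_act.size();
  const int ne = elec.nrow();
  NumericMatrix vals(nt, ne);
  IntegerVector n_active(nt);
  NumericVector x = clone(x0), y = clone(y0);
  LogicalVector active = clone(active0);
  const double inv2k2 = 1.0 / (2.0 * kscale * kscale);
  // drop contributions below 1e-4 of full coupling
  const double cutoff_d2 = 2.0 * kscale * kscale * 9.2103403719761836;

  // contribution cache: C[m][e] and per-electrode running sums
  std::vector<double> C((size_t)std::max(n_mice, 1) * ne, 0.0);
  std::vector<double> sumv(ne, 0.0);
  for (int m = 0; m < n_mice; ++m) {
    for (int e = 0; e < ne; ++e) {
      const double dx = x[m] - elec(e, 0);
      const double dy = y[m] - elec(e, 1);
      const double d2 = dx * dx + dy * dy;
      const double c = (d2 < cutoff_d2) ? coupling[m] * std::exp(-d2 * inv2k2)
                                        : 0.0;
      C[(size_t)m * ne + e] = c;
      sumv[e] += c;
    }
  }

  for (int t = 0; t < nt; ++t) {
    int na = 0;
    for (int m = 0; m < n_mice; ++m) {
      const double u = trans(t, m);
      if (active[m]) {
        x[m] = reflect1(x[m] + norm_rand() * step_sd, xmin, xmax);
        y[m] = reflect1(y[m] + norm_rand() * step_sd, ymin, ymax);
        for (int e = 0; e < ne; ++e) {
          const double dx = x[m] - elec(e, 0);
          const double dy = y[m] - elec(e, 1);
          const double d2 = dx * dx + dy * dy;
          const double c = (d2 < cutoff_d2)
            ? coupling[m] * std::exp(-d2 * inv2k2) : 0.0;
          sumv[e] += c - C[(size_t)m * ne + e];
          C[(size_t)m * ne + e] = c;
        }
        if (u < p_rest) active[m] = FALSE;
      } else if (u < p_act[t]) {
        active[m] = TRUE;
      }
      if (active[m]) ++na;
    }
    n_active[t] = na;
    for (int e = 0; e < ne; ++e) {
      vals(t, e) = baseline[e] + sumv[e] + sigma[e] * noise(t, e);
    }
  }
  return List::create(_["values"] = vals, _["x"] = x, _["y"] = y,
                      _["active"] = active, _["n_active"] = n_active);
}
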