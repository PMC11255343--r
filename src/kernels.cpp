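#include <Rcpp.h>
using namespace Rcpp;

// linear interpolation on a uniform grid; clamped at the ends
static inline double interp_uniform(const NumericVector& y, double x0,
                                    double dx, int n, double x) {
  double u = (x - x0) / dx;
  if (u <= 0.0) return y[0];
  if (u >= n - 1) return y[n - 1];
  int i = (int)u;
  double f = u - i;
  return y[i] * (1.0 - f) + y[i + 1] * f;
}

// Overdamped Langevin (Euler-Maruyama) for the end-to-end distance in a
// potential of mean force: dr = D * dlnP/dr * dt + sqrt(2 D dt) dW, with
// reflecting boundaries at [rmin, rmax]. The drift table dlnp holds
// d ln P / dr on a uniform grid starting at grid0 with spacing dgrid.
// Uses the R RNG (seed with set.seed()).
// [[Rcpp::export]]
NumericVector bd_simulate_cpp(double r0, double D, double dt, int n_steps,
                              NumericVector dlnp, double grid0,
                              double dgrid, double rmin, double rmax,
                              int thin) {
  int ng = dlnp.size();
  int n_out = n_steps / thin;
  NumericVector out(n_out);
  double r = r0;
  double amp = std::sqrt(2.0 * D * dt);
  double max_drift = 3.0 * amp;  // clamp deep-tail forces to noise scale
  int k = 0;
  for (int i = 0; i < n_steps; ++i) {
    double dstep = D * interp_uniform(dlnp, grid0, dgrid, ng, r) * dt;
    if (dstep > max_drift) dstep = max_drift;
    if (dstep < -max_drift) dstep = -max_drift;
    r += dstep + amp * norm_rand();
    if (r < rmin) r = 2.0 * rmin - r;
    if (r > rmax) r = 2.0 * rmax - r;
    if (r < rmin) r = rmin;  // pathological double-bounce
    if ((i + 1) % thin == 0 && k < n_out) out[k++] = r;
  }
  return out;
}

// First-passage times to an absorbing boundary at r = a (from below in
// distance, i.e. contact formation), starting from supplied initial
// distances. Returns passage time in ns for each start (NA if not
// reached within n_steps).
// [[Rcpp::export]]
NumericVector bd_first_passage_cpp(NumericVector r_init, double a,
                                   double D, double dt, int n_steps,
                                   NumericVector dlnp, double grid0,
                                   double dgrid, double rmin, double rmax) {
  int ns = r_init.size();
  int ng = dlnp.size();
  NumericVector out(ns, NA_REAL);
  double amp = std::sqrt(2.0 * D * dt);
  double max_drift = 3.0 * amp;
  for (int s = 0; s < ns; ++s) {
    double r = r_init[s];
    if (r <= a) { out[s] = 0.0; continue; }
    for (int i = 0; i < n_steps; ++i) {
      double dstep = D * interp_uniform(dlnp, grid0, dgrid, ng, r) * dt;
      if (dstep > max_drift) dstep = max_drift;
      if (dstep < -max_drift) dstep = -max_drift;
      r += dstep + amp * norm_rand();
      if (r > rmax) r = 2.0 * rmax - r;
      if (r <= a) { out[s] = (i + 1) * dt; break; }
    }
  }
  return out;
}

// Photon-pair counts: number of ordered pairs (i from t1, j from t2) with
// lag t2[j] - t1[i] in [edges[k], edges[k+1]). Both streams must be
// sorted ascending. If burst ids are supplied (same length as the
// streams), only pairs within the same burst are counted.
// [[Rcpp::export]]
NumericVector pair_counts_cpp(NumericVector t1, NumericVector t2,
                              NumericVector edges,
                              IntegerVector id1, IntegerVector id2) {
  int n1 = t1.size(), n2 = t2.size(), nb = edges.size() - 1;
  bool use_id = (id1.size() == n1) && (id2.size() == n2) && n1 > 0;
  NumericVector counts(nb);
  double e0 = edges[0], emax = edges[nb];
  int lo = 0;
  for (int i = 0; i < n1; ++i) {
    double tmin = t1[i] + e0, tmax = t1[i] + emax;
    while (lo < n2 && t2[lo] < tmin) ++lo;
    for (int j = lo; j < n2 && t2[j] < tmax; ++j) {
      if (use_id && id1[i] != id2[j]) continue;
      double lag = t2[j] - t1[i];
      // binary search for the lag bin
      int a = 0, b = nb;
      while (b - a > 1) {
        int m = (a + b) / 2;
        if (lag >= edges[m]) a = m; else b = m;
      }
      counts[a] += 1.0;
    }
  }
  return counts;
}
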