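#include <Rcpp.h>
#include <map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---- potential surrogate -------------------------------------------------
// U(d) = tilt*(d-mid)/span + sum_s A_s*cos(2*pi*(d-anchor)/lambda_s + phi_s)
//        + 0.5*wall_k*(max(0,dlo-d)^2 + max(0,d-dhi)^2)
static inline double pot_u(double d, const double* amp, const double* wav,
                           const double* phs, int ns, double anchor,
                           double tilt, double mid, double span,
                           double dlo, double dhi, double wallk) {
  double u = tilt * (d - mid) / span;
  for (int s = 0; s < ns; ++s)
    u += amp[s] * std::cos(2.0 * M_PI * (d - anchor) / wav[s] + phs[s]);
  double lo = dlo - d, hi = d - dhi;
  if (lo > 0) u += 0.5 * wallk * lo * lo;
  if (hi > 0) u += 0.5 * wallk * hi * hi;
  return u;
}

static inline double pot_f(double d, const double* amp, const double* wav,
                           const double* phs, int ns, double anchor,
                           double tilt, double mid, double span,
                           double dlo, double dhi, double wallk) {
  // force = -dU/dd
  double du = tilt / span;
  for (int s = 0; s < ns; ++s) {
    double w = 2.0 * M_PI / wav[s];
    du += -amp[s] * w * std::sin(w * (d - anchor) + phs[s]);
  }
  if (d < dlo) du += -wallk * (dlo - d);
  if (d > dhi) du += wallk * (d - dhi);
  return -du;
}

// [[Rcpp::export]]
NumericVector cpp_potential_energy(NumericVector d, NumericVector amp,
                                   NumericVector wav, NumericVector phs,
                                   double anchor, double tilt, double dlo,
                                   double dhi, double wallk) {
  int n = d.size(), ns = amp.size();
  double mid = 0.5 * (dlo + dhi), span = dhi - dlo;
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = pot_u(d[i], amp.begin(), wav.begin(), phs.begin(), ns, anchor,
                   tilt, mid, span, dlo, dhi, wallk);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_potential_force(NumericVector d, NumericVector amp,
                                  NumericVector wav, NumericVector phs,
                                  double anchor, double tilt, double dlo,
                                  double dhi, double wallk) {
  int n = d.size(), ns = amp.size();
  double mid = 0.5 * (dlo + dhi), span = dhi - dlo;
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = pot_f(d[i], amp.begin(), wav.begin(), phs.begin(), ns, anchor,
                   tilt, mid, span, dlo, dhi, wallk);
  return out;
}

// ---- Brownian dynamics (Euler-Maruyama, 1-D) -----------------------------
// x_{t+1} = x_t + (D/kBT) F(x_t) dt + sqrt(2 D dt) eta.  Uses the R RNG so
// trajectories are reproducible under set.seed().
// Returns an m x k matrix; column j is trajectory j, starting at x0.
// [[Rcpp::export]]
NumericMatrix cpp_bd_simulate(double x0, int k, int m, double D, double kT,
                              double dt, NumericVector amp, NumericVector wav,
                              NumericVector phs, double anchor, double tilt,
                              double dlo, double dhi, double wallk) {
  int ns = amp.size();
  double mid = 0.5 * (dlo + dhi), span = dhi - dlo;
  double mob = D / kT * dt, sig = std::sqrt(2.0 * D * dt);
  NumericMatrix out(m, k);
  for (int j = 0; j < k; ++j) {
    double x = x0;
    out(0, j) = x;
    for (int t = 1; t < m; ++t) {
      double f = pot_f(x, amp.begin(), wav.begin(), phs.begin(), ns, anchor,
                       tilt, mid, span, dlo, dhi, wallk);
      x += mob * f + sig * norm_rand();
      out(t, j) = x;
    }
  }
  return out;
}

// ---- discrete chain sampler ----------------------------------------------
// cum: n x n matrix of row-wise cumulative transition probabilities.
// Returns an m x k integer matrix of 1-based state indices.
// [[Rcpp::export]]
IntegerMatrix cpp_chain_simulate(NumericMatrix cum, int s0, int k, int m) {
  int n = cum.nrow();
  IntegerMatrix out(m, k);
  for (int j = 0; j < k; ++j) {
    int s = s0 - 1;
    out(0, j) = s + 1;
    for (int t = 1; t < m; ++t) {
      double u = unif_rand();
      int nxt = n - 1;
      for (int c = 0; c < n; ++c) {
        if (u <= cum(s, c)) { nxt = c; break; }
      }
      s = nxt;
      out(t, j) = s + 1;
    }
  }
  return out;
}

// ---- online K-centers assignment -----------------------------------------
static inline double sqdist(const double* a, const double* b, int F,
                            const int* per, const double* period) {
  double s = 0.0;
  for (int f = 0; f < F; ++f) {
    double d = std::fabs(a[f] - b[f]);
    if (per[f]) {
      double w = period[f] - d;
      if (w < d) d = w;
    }
    s += d * d;
  }
  return s;
}

// Assign frames (m x F) to microstates under the online K-centers rule:
// nearest existing center within `radius` wins (ties -> lowest id), else the
// frame becomes a new center.  `centers` holds the pre-existing centers
// (n0 x F).  Returns 1-based ids per frame, the new centers in creation
// order, and for each new center the id of its nearest center at creation
// time (0 when none existed).  A fast ordered-map path is used for a single
// aperiodic feature; the general path is a linear scan.
// [[Rcpp::export]]
List cpp_kcenters_assign(NumericMatrix frames, NumericMatrix centers,
                         double radius, LogicalVector periodic,
                         NumericVector period) {
  int m = frames.nrow(), F = frames.ncol(), n0 = centers.nrow();
  std::vector<int> per(F);
  for (int f = 0; f < F; ++f) per[f] = periodic[f] ? 1 : 0;
  double r2 = radius * radius;

  std::vector<std::vector<double>> cent;
  cent.reserve(n0 + 64);
  for (int i = 0; i < n0; ++i) {
    std::vector<double> c(F);
    for (int f = 0; f < F; ++f) c[f] = centers(i, f);
    cent.push_back(c);
  }
  IntegerVector ids(m);
  std::vector<int> nearest_prev;
  std::vector<double> newc;

  bool fast1d = (F == 1 && !per[0]);
  std::map<double, int> idx;  // center coordinate -> 0-based id (1-D path)
  if (fast1d)
    for (int i = 0; i < n0; ++i) idx[cent[i][0]] = i;

  for (int t = 0; t < m; ++t) {
    const double* x = &frames(t, 0);  // column-major: only valid when F==1
    std::vector<double> xv(F);
    for (int f = 0; f < F; ++f) xv[f] = frames(t, f);
    int best = -1;
    double bestd = R_PosInf;
    if (fast1d) {
      double v = xv[0];
      if (!idx.empty()) {
        std::map<double, int>::iterator hi = idx.lower_bound(v);
        if (hi != idx.end()) {
          double d = std::fabs(hi->first - v);
          if (d < bestd || (d == bestd && hi->second < best)) {
            bestd = d; best = hi->second;
          }
        }
        if (hi != idx.begin()) {
          --hi;
          double d = std::fabs(hi->first - v);
          if (d < bestd || (d == bestd && hi->second < best)) {
            bestd = d; best = hi->second;
          }
        }
      }
      bestd = bestd * bestd;
    } else {
      for (size_t i = 0; i < cent.size(); ++i) {
        double d = sqdist(xv.data(), cent[i].data(), F, per.data(),
                          period.begin());
        if (d < bestd) { bestd = d; best = (int)i; }
      }
    }
    if (best >= 0 && bestd <= r2) {
      ids[t] = best + 1;
    } else {
      int id = (int)cent.size();
      cent.push_back(xv);
      if (fast1d) idx[xv[0]] = id;
      nearest_prev.push_back(best + 1);  // 0 when no center existed
      for (int f = 0; f < F; ++f) newc.push_back(xv[f]);
      ids[t] = id + 1;
    }
    (void)x;
  }

  int nnew = (int)nearest_prev.size();
  NumericMatrix nc(nnew, F);
  for (int i = 0; i < nnew; ++i)
    for (int f = 0; f < F; ++f) nc(i, f) = newc[(size_t)i * F + f];
  return List::create(_["ids"] = ids, _["new_centers"] = nc,
                      _["nearest_prev"] = wrap(nearest_prev));
}

// First frame index (1-based) falling in each of nbins equal-width bins over
// [lo, lo + nbins*w); 0 for bins never visited.
// [[Rcpp::export]]
IntegerVector cpp_bin_first_visit(NumericVector x, double lo, double w,
                                  int nbins) {
  IntegerVector first(nbins);
  int n = x.size();
  for (int t = 0; t < n; ++t) {
    int b = (int)std::floor((x[t] - lo) / w);
    if (b >= 0 && b < nbins && first[b] == 0) first[b] = t + 1;
  }
  return first;
}
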