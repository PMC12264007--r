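#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exact maximizer of the 1D restriction of the SVR dual along
// e_i - e_j, handling the |theta| kinks segment-wise (mirrors the R
// reference implementation used for the toy-scale tests).
static double pair_step(double ti, double tj, double Kii, double Kjj,
                        double Kij, double gi, double gj, double eps,
                        double C) {
  const double eta = Kii + Kjj - 2.0 * Kij;
  const double dmax = std::min(C - ti, tj + C);
  if (dmax <= 0) return 0.0;
  double bps[4];
  int nb = 0;
  bps[nb++] = 0.0;
  if (ti < 0 && -ti < dmax) bps[nb++] = -ti;
  if (tj > 0 && tj < dmax) bps[nb++] = tj;
  bps[nb++] = dmax;
  std::sort(bps, bps + nb);
  double best_delta = 0.0, best_gain = 0.0;
  for (int s = 0; s + 1 < nb; ++s) {
    const double lo = bps[s], hi = bps[s + 1];
    if (hi <= lo) continue;
    const double mid = 0.5 * (lo + hi);
    const double si = (ti + mid >= 0) ? 1.0 : -1.0;
    const double sj = (tj - mid >= 0) ? 1.0 : -1.0;
    const double slope0 = (gi - gj) - eps * si + eps * sj;
    double cand;
    if (eta > 0) {
      cand = slope0 / eta;
      if (cand < lo) cand = lo;
      if (cand > hi) cand = hi;
    } else {
      cand = (slope0 > 0) ? hi : lo;
    }
    const double pts[3] = {lo, cand, hi};
    for (int q = 0; q < 3; ++q) {
      const double d = pts[q];
      const double gain = (gi - gj) * d - 0.5 * eta * d * d
        - eps * (std::fabs(ti + d) - std::fabs(ti))
        - eps * (std::fabs(tj - d) - std::fabs(tj));
      if (gain > best_gain) { best_gain = gain; best_delta = d; }
    }
  }
  return best_delta;
}

static inline double snap_box(double t, double C) {
  const double tol = 1e-12 * std::max(1.0, C);
  if (std::fabs(t) < tol) return 0.0;
  if (std::fabs(t - C) < tol) return C;
  if (std::fabs(t + C) < tol) return -C;
  return t;
}

// SMO loop on theta = a - a*, keeping sum(theta) = 0 exact.  The
// ascent coordinate is drawn (via R's RNG, so seeded from R) among the
// top violators; the partner is the max-violating descent coordinate.
// The incremental K*theta cache is refreshed exactly every `refresh`
// updates to kill rounding drift.
// [[Rcpp::export]]
List smo_solve(const NumericMatrix& K, const NumericVector& y,
               double eps, double C, double tol, int max_iter,
               int refresh = 2000, int topk = 8) {
  const int n = y.size();
  std::vector<double> theta(n, 0.0), Kth(n, 0.0);
  double violation = R_PosInf;
  int iter = 0;
  std::vector<int> top(topk);
  while (iter < max_iter) {
    if (iter > 0 && iter % refresh == 0) {
      for (int r = 0; r < n; ++r) Kth[r] = 0.0;
      for (int c = 0; c < n; ++c) {
        const double t = theta[c];
        if (t != 0.0) {
          const double* col = &K(0, c);
          for (int r = 0; r < n; ++r) Kth[r] += t * col[r];
        }
      }
    }
    // d_up / d_dn and their maxima; collect top-k ascent candidates
    double best_up = -R_PosInf, best_dn = -R_PosInf;
    int i_up = -1, j_dn = -1;
    int ntop = 0;
    for (int r = 0; r < n; ++r) {
      const double g = y[r] - Kth[r];
      const double du = (theta[r] >= C) ? -R_PosInf
        : ((theta[r] >= 0) ? g - eps : g + eps);
      const double dd = (theta[r] <= -C) ? -R_PosInf
        : ((theta[r] > 0) ? -(g - eps) : -(g + eps));
      if (du > best_up) { best_up = du; i_up = r; }
      if (dd > best_dn) { best_dn = dd; j_dn = r; }
      if (du > 0 && R_FINITE(du)) {
        if (ntop < topk) top[ntop++] = r;
        else {
          // replace the weakest stored candidate if this one is stronger
          int wmin = 0;
          double vmin = R_PosInf;
          for (int q = 0; q < topk; ++q) {
            const double g2 = y[top[q]] - Kth[top[q]];
            const double v2 = (theta[top[q]] >= 0) ? g2 - eps : g2 + eps;
            if (v2 < vmin) { vmin = v2; wmin = q; }
          }
          if (du > vmin) top[wmin] = r;
        }
      }
    }
    violation = best_up + best_dn;
    if (!R_FINITE(violation) || violation <= tol) break;
    // seeded draw among stored ascent candidates (weight ~ violation)
    int i = i_up;
    if (ntop > 1) {
      double wsum = 0.0;
      std::vector<double> w(ntop);
      for (int q = 0; q < ntop; ++q) {
        const double g2 = y[top[q]] - Kth[top[q]];
        w[q] = (theta[top[q]] >= 0) ? g2 - eps : g2 + eps;
        wsum += w[q];
      }
      double u = unif_rand() * wsum, acc = 0.0;
      for (int q = 0; q < ntop; ++q) {
        acc += w[q];
        if (u <= acc) { i = top[q]; break; }
      }
    }
    int j = j_dn;
    if (j == i) {
      double bd = -R_PosInf;
      j = -1;
      for (int r = 0; r < n; ++r) {
        if (r == i) continue;
        const double g = y[r] - Kth[r];
        const double dd = (theta[r] <= -C) ? -R_PosInf
          : ((theta[r] > 0) ? -(g - eps) : -(g + eps));
        if (dd > bd) { bd = dd; j = r; }
      }
      if (j < 0) break;
    }
    const double gi = y[i] - Kth[i], gj = y[j] - Kth[j];
    const double delta = pair_step(theta[i], theta[j], K(i, i), K(j, j),
                                   K(i, j), gi, gj, eps, C);
    if (delta > 0) {
      theta[i] = snap_box(theta[i] + delta, C);
      theta[j] = snap_box(theta[j] - delta, C);
      const double* ci = &K(0, i);
      const double* cj = &K(0, j);
      for (int r = 0; r < n; ++r) Kth[r] += delta * (ci[r] - cj[r]);
    }
    ++iter;
  }
  // exact final cache and violation
  NumericVector th(n), kth(n);
  for (int r = 0; r < n; ++r) th[r] = theta[r];
  for (int r = 0; r < n; ++r) kth[r] = 0.0;
  for (int c = 0; c < n; ++c) {
    if (theta[c] != 0.0) {
      const double* col = &K(0, c);
      for (int r = 0; r < n; ++r) kth[r] += theta[c] * col[r];
    }
  }
  double best_up = -R_PosInf, best_dn = -R_PosInf;
  for (int r = 0; r < n; ++r) {
    const double g = y[r] - kth[r];
    const double du = (th[r] >= C) ? -R_PosInf
      : ((th[r] >= 0) ? g - eps : g + eps);
    const double dd = (th[r] <= -C) ? -R_PosInf
      : ((th[r] > 0) ? -(g - eps) : -(g + eps));
    if (du > best_up) best_up = du;
    if (dd > best_dn) best_dn = dd;
  }
  violation = best_up + best_dn;
  return List::create(_["theta"] = th, _["Ktheta"] = kth,
                      _["violation"] = violation, _["iter"] = iter);
}
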