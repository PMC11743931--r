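#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Stretch springs: U = (k/2) (r0 - |bi - bj|)^2.
// Bending triples:  U = (kb/2) (theta - theta0)^2, theta the interior angle
// at the middle bead.  Forces are the exact analytic gradients; the
// (theta - theta0)/sin(theta) factor is continuous through the straight
// configuration theta = theta0 = pi.
static void accumulate_forces(const NumericMatrix& pos,
                              const IntegerVector& bi, const IntegerVector& bj,
                              const NumericVector& bk, const NumericVector& br0,
                              const IntegerVector& ai, const IntegerVector& aj,
                              const IntegerVector& ak, const NumericVector& akb,
                              const NumericVector& ath0,
                              NumericMatrix& F, double* energy,
                              bool strict) {
  const int nb = bi.size(), na = ai.size();
  double U = 0.0;
  for (int e = 0; e < nb; ++e) {
    const int i = bi[e], j = bj[e];
    const double dx = pos(i, 0) - pos(j, 0), dy = pos(i, 1) - pos(j, 1);
    const double r = std::sqrt(dx * dx + dy * dy);
    const double dr = br0[e] - r;
    U += 0.5 * bk[e] * dr * dr;
    if (r < 1e-12) continue;           // coincident beads: no direction
    const double fmag = bk[e] * dr / r;  // >0 pushes i away from j
    F(i, 0) += fmag * dx;
    F(i, 1) += fmag * dy;
    F(j, 0) -= fmag * dx;
    F(j, 1) -= fmag * dy;
  }
  for (int t = 0; t < na; ++t) {
    const int i = ai[t], j = aj[t], k = ak[t];
    const double ux = pos(i, 0) - pos(j, 0), uy = pos(i, 1) - pos(j, 1);
    const double wx = pos(k, 0) - pos(j, 0), wy = pos(k, 1) - pos(j, 1);
    const double ru2 = ux * ux + uy * uy, rw2 = wx * wx + wy * wy;
    const double ru = std::sqrt(ru2), rw = std::sqrt(rw2);
    if (ru < 1e-12 || rw < 1e-12) {
      // coincident beads: the angle is undefined.  Exported operations
      // treat this as an error; the integrator skips the triple (it can
      // arise transiently when two adhesions share a lattice site).
      if (strict) stop("degenerate angle triple: coincident beads");
      continue;
    }
    double c = (ux * wx + uy * wy) / (ru * rw);
    if (c > 1.0) c = 1.0;
    if (c < -1.0) c = -1.0;
    const double theta = std::acos(c);
    const double dth = theta - ath0[t];
    U += 0.5 * akb[t] * dth * dth;
    const double s = std::sqrt(1.0 - c * c);
    // The gradient magnitude kb*(theta-theta0)/ru stays finite as s -> 0:
    // at theta ~ theta0 = pi the force vanishes, and at theta ~ 0 (fully
    // folded) its direction is undefined by symmetry.  Skip both.
    if (s < 1e-8) continue;
    const double g = akb[t] * dth / s;
    // dU/dbi = g * (c*u/ru^2 - w/(ru*rw))  (chain rule through acos)
    const double fix = g * (c * ux / ru2 - wx / (ru * rw));
    const double fiy = g * (c * uy / ru2 - wy / (ru * rw));
    const double fkx = g * (c * wx / rw2 - ux / (ru * rw));
    const double fky = g * (c * wy / rw2 - uy / (ru * rw));
    F(i, 0) -= fix;
    F(i, 1) -= fiy;
    F(k, 0) -= fkx;
    F(k, 1) -= fky;
    F(j, 0) += fix + fkx;
    F(j, 1) += fiy + fky;
  }
  if (energy) *energy = U;
}

// [[Rcpp::export]]
List cpp_network_forces(const NumericMatrix& pos,
                        const IntegerVector& bi, const IntegerVector& bj,
                        const NumericVector& bk, const NumericVector& br0,
                        const IntegerVector& ai, const IntegerVector& aj,
                        const IntegerVector& ak, const NumericVector& akb,
                        const NumericVector& ath0, bool strict = true) {
  NumericMatrix F(pos.nrow(), 2);
  double U = 0.0;
  accumulate_forces(pos, bi, bj, bk, br0, ai, aj, ak, akb, ath0, F, &U,
                    strict);
  return List::create(_["forces"] = F, _["energy"] = U);
}

// Overdamped integrator b <- b + (dt/gamma) (F + W) for free beads.
// Noise W has per-component variance gamma*T_ecm/dt so that the mean
// squared noise magnitude is 2*gamma*T_ecm/dt.  Convergence is tested on
// the maximum potential force over free beads every check_every substeps.
// [[Rcpp::export]]
List cpp_relax(const NumericMatrix& pos_in,
               const IntegerVector& bi, const IntegerVector& bj,
               const NumericVector& bk, const NumericVector& br0,
               const IntegerVector& ai, const IntegerVector& aj,
               const IntegerVector& ak, const NumericVector& akb,
               const NumericVector& ath0,
               const LogicalVector& free_bead,
               double gamma, double T_ecm, double dt,
               int max_steps, double force_tol, int check_every) {
  NumericMatrix pos = clone(pos_in);
  const int n = pos.nrow();
  NumericMatrix F(n, 2);
  const double mob = dt / gamma;
  const double noise_sd = T_ecm > 0 ? std::sqrt(gamma * T_ecm / dt) : 0.0;
  bool converged = false;
  int steps = 0;
  for (int it = 0; it < max_steps; ++it) {
    std::fill(F.begin(), F.end(), 0.0);
    accumulate_forces(pos, bi, bj, bk, br0, ai, aj, ak, akb, ath0, F, 0,
                      false);
    const bool check = (it % check_every == 0) || (it == max_steps - 1);
    double fmax = 0.0;
    for (int b = 0; b < n; ++b) {
      if (!free_bead[b]) continue;
      if (check) {
        const double fm = std::fabs(F(b, 0)) + std::fabs(F(b, 1));
        if (fm > fmax) fmax = fm;
      }
      double wx = 0.0, wy = 0.0;
      if (noise_sd > 0) {
        wx = noise_sd * norm_rand();
        wy = noise_sd * norm_rand();
      }
      pos(b, 0) += mob * (F(b, 0) + wx);
      pos(b, 1) += mob * (F(b, 1) + wy);
    }
    ++steps;
    if (check && fmax < force_tol) {
      converged = true;
      break;
    }
  }
  return List::create(_["pos"] = pos, _["converged"] = converged,
                      _["steps"] = steps);
}
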