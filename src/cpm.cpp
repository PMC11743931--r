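#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Moore (second-order) stencil, ordered row-wise.
static const int MOORE_DI[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int MOORE_DJ[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// Hamiltonian H = lambda*A^2 + J * (# ordered mismatched neighbour pairs)
//               - lambda_c * A / (A + A_h).
// Off-grid neighbours contribute no pairs; the cell is kept away from the
// boundary ring by the dynamics, so this convention never matters in runs.
// [[Rcpp::export]]
double cpp_cpm_energy(const IntegerMatrix& grid, double lambda, double J,
                      double lambda_c, double A_h) {
  const int nr = grid.nrow(), nc = grid.ncol();
  long A = 0, mism = 0;
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      const int s = grid(i, j);
      if (s > 0) ++A;
      for (int k = 0; k < 8; ++k) {
        const int ni = i + MOORE_DI[k], nj = j + MOORE_DJ[k];
        if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
        if (grid(ni, nj) != s) ++mism;
      }
    }
  }
  double H = lambda * (double)A * (double)A + J * (double)mism;
  if (A > 0) H -= lambda_c * (double)A / ((double)A + A_h);
  return H;
}

// Change in the ordered mismatched-pair count if grid(i, j) flips to
// new_spin (i, j are 0-based).
// [[Rcpp::export]]
int cpp_interface_delta(const IntegerMatrix& grid, int i, int j,
                        int new_spin) {
  const int nr = grid.nrow(), nc = grid.ncol();
  const int s = grid(i, j);
  int delta = 0;
  for (int k = 0; k < 8; ++k) {
    const int ni = i + MOORE_DI[k], nj = j + MOORE_DJ[k];
    if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
    const int n = grid(ni, nj);
    delta += 2 * ((new_spin != n) - (s != n));  // each unordered pair twice
  }
  return delta;
}

static inline double adhesion_term(double A, double lambda_c, double A_h) {
  return A > 0 ? lambda_c * A / (A + A_h) : 0.0;
}

// Hill-saturated retraction penalty lambda_FA * X / (X + N_h),
// X = max(0, sum(N - N0)) over the FAs at the site.
static inline double fa_penalty(double sumN, int n_fas, double N0,
                                double N_h, double lambda_FA) {
  if (n_fas == 0) return 0.0;
  double X = sumN - n_fas * N0;
  if (X <= 0) return 0.0;
  return lambda_FA * X / (X + N_h);
}

// One Monte Carlo step: n_attempts elementary copy attempts.
// grid is modified by reference semantics on a clone; the FA registry and
// bead bindings are updated for FA removal (accepted retraction over a
// site with FAs) and creation (accepted extension over a site holding at
// least one free bead).  Uses R's RNG (unif_rand) throughout.
// [[Rcpp::export]]
List cpp_monte_carlo_step(IntegerMatrix grid_in, int n_attempts,
                          double lambda, double J, double lambda_c,
                          double A_h, double T,
                          IntegerVector fa_site, NumericVector fa_N,
                          IntegerVector fa_bead,
                          double N0, double N_h, double lambda_FA,
                          NumericMatrix bead_pos_in, LogicalVector bead_free_in,
                          double lattice_spacing, bool forbid_boundary) {
  IntegerMatrix grid = clone(grid_in);
  NumericMatrix bead_pos = clone(bead_pos_in);
  LogicalVector bead_free = clone(bead_free_in);
  const int nr = grid.nrow(), nc = grid.ncol();
  const int n_sites = nr * nc;
  const int n_fas = fa_site.size();
  const int n_beads = bead_pos.nrow();

  long A = 0;
  for (int i = 0; i < n_sites; ++i) if (grid[i] > 0) ++A;

  // per-site FA bookkeeping (sites are column-major linear indices).
  // Indices >= n_fas refer to FAs created earlier in this same sweep, so
  // that a later retraction over the site removes them too.
  std::vector<std::vector<int> > site_fas(n_sites);
  std::vector<bool> fa_alive(n_fas, true);
  std::vector<bool> new_alive;
  for (int f = 0; f < n_fas; ++f) {
    if (fa_site[f] < 0 || fa_site[f] >= n_sites)
      stop("FA site index out of range");
    site_fas[fa_site[f]].push_back(f);
  }

  // per-site free beads (inside-domain beads only)
  std::vector<std::vector<int> > site_beads(n_sites);
  std::vector<int> bead_site(n_beads, -1);
  for (int b = 0; b < n_beads; ++b) {
    if (!bead_free[b]) continue;
    int bi = (int)std::floor(bead_pos(b, 0) / lattice_spacing);
    int bj = (int)std::floor(bead_pos(b, 1) / lattice_spacing);
    if (bi < 0 || bi >= nr || bj < 0 || bj >= nc) continue;
    int lin = bi + bj * nr;
    bead_site[b] = lin;
    site_beads[lin].push_back(b);
  }

  std::vector<int> created_bead, created_site;
  std::vector<int> ev_src, ev_tgt, ev_kind, ev_fa_created, ev_fa_removed;

  for (int att = 0; att < n_attempts; ++att) {
    const int src = (int)(unif_rand() * n_sites);
    if (src >= n_sites) continue;
    const int si = src % nr, sj = src / nr;
    const int k = (int)(unif_rand() * 8);
    const int ti = si + MOORE_DI[k], tj = sj + MOORE_DJ[k];
    if (ti < 0 || ti >= nr || tj < 0 || tj >= nc) continue;
    if (forbid_boundary &&
        (ti == 0 || ti == nr - 1 || tj == 0 || tj == nc - 1)) continue;
    const int s_src = grid(si, sj), s_tgt = grid(ti, tj);
    if (s_src == s_tgt) continue;
    const bool extension = (s_src > 0);
    const int tgt = ti + tj * nr;

    const double dA = extension ? 1.0 : -1.0;
    double dH = lambda * ((double)A + dA) * ((double)A + dA)
              - lambda * (double)A * (double)A;
    dH += J * (double)cpp_interface_delta(grid, ti, tj, s_src);
    dH -= adhesion_term((double)A + dA, lambda_c, A_h)
        - adhesion_term((double)A, lambda_c, A_h);

    if (!extension && !site_fas[tgt].empty()) {
      double sumN = 0.0;
      int live = 0;
      for (size_t q = 0; q < site_fas[tgt].size(); ++q) {
        int f = site_fas[tgt][q];
        if (f < n_fas ? !fa_alive[f] : !new_alive[f - n_fas]) continue;
        sumN += (f < n_fas) ? fa_N[f] : N0;  // sweep-created FAs have N = N0
        ++live;
      }
      dH += fa_penalty(sumN, live, N0, N_h, lambda_FA);
    }

    bool accept = dH <= 0.0;
    if (!accept) accept = unif_rand() < std::exp(-dH / T);
    if (!accept) continue;

    grid(ti, tj) = s_src;
    A += extension ? 1 : -1;

    int created_here = -1;
    int removed_here = 0;
    if (!extension) {
      // retraction: any FA left outside the cell at the target is removed
      for (size_t q = 0; q < site_fas[tgt].size(); ++q) {
        int f = site_fas[tgt][q];
        if (f < n_fas ? !fa_alive[f] : !new_alive[f - n_fas]) continue;
        if (f < n_fas) fa_alive[f] = false; else new_alive[f - n_fas] = false;
        ++removed_here;
        int b = (f < n_fas) ? fa_bead[f] : created_bead[f - n_fas];
        if (b >= 0 && b < n_beads) {       // bead becomes free again
          bead_free[b] = true;
          int bi = (int)std::floor(bead_pos(b, 0) / lattice_spacing);
          int bj = (int)std::floor(bead_pos(b, 1) / lattice_spacing);
          if (bi >= 0 && bi < nr && bj >= 0 && bj < nc) {
            bead_site[b] = bi + bj * nr;
            site_beads[bead_site[b]].push_back(b);
          }
        }
      }
      site_fas[tgt].clear();
    } else if (!site_beads[tgt].empty()) {
      // extension over >= 1 free bead: bind the bead nearest the site
      // centre (lowest index on ties) into a new nascent FA
      const double cx = (ti + 0.5) * lattice_spacing;
      const double cy = (tj + 0.5) * lattice_spacing;
      int best = -1;
      double best_d2 = R_PosInf;
      for (size_t q = 0; q < site_beads[tgt].size(); ++q) {
        int b = site_beads[tgt][q];
        if (!bead_free[b]) continue;
        double dx = bead_pos(b, 0) - cx, dy = bead_pos(b, 1) - cy;
        double d2 = dx * dx + dy * dy;
        if (d2 < best_d2 - 1e-15 ||
            (std::abs(d2 - best_d2) <= 1e-15 && b < best)) {
          best = b;
          best_d2 = d2;
        }
      }
      if (best >= 0) {
        bead_free[best] = false;
        bead_pos(best, 0) = cx;             // pin to the site centre
        bead_pos(best, 1) = cy;
        std::vector<int>& v = site_beads[tgt];
        v.erase(std::remove(v.begin(), v.end(), best), v.end());
        site_fas[tgt].push_back(n_fas + (int)created_bead.size());
        created_bead.push_back(best);
        created_site.push_back(tgt);
        new_alive.push_back(true);
        created_here = best;
      }
    }

    ev_src.push_back(src);
    ev_tgt.push_back(tgt);
    ev_kind.push_back(extension ? 1 : 2);
    ev_fa_created.push_back(created_here);
    ev_fa_removed.push_back(removed_here);
  }

  LogicalVector alive(n_fas);
  for (int f = 0; f < n_fas; ++f) alive[f] = fa_alive[f];
  std::vector<int> keep_bead, keep_site;   // sweep-created FAs still alive
  for (size_t q = 0; q < created_bead.size(); ++q) {
    if (!new_alive[q]) continue;
    keep_bead.push_back(created_bead[q]);
    keep_site.push_back(created_site[q]);
  }

  return List::create(
      _["grid"] = grid, _["area"] = (double)A, _["fa_alive"] = alive,
      _["created_bead"] = wrap(keep_bead),
      _["created_site"] = wrap(keep_site),
      _["bead_pos"] = bead_pos, _["bead_free"] = bead_free,
      _["ev_source"] = wrap(ev_src), _["ev_target"] = wrap(ev_tgt),
      _["ev_kind"] = wrap(ev_kind),
      _["ev_fa_created"] = wrap(ev_fa_created),
      _["ev_fa_removed"] = wrap(ev_fa_removed));
}
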