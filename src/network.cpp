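#include <Rcpp.h>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

// All bead pairs on distinct fibers closer than `radius`, found with a
// uniform cell list (bin edge = radius).  Returns a 2-column matrix of
// 0-based bead indices with i < j; each unordered pair appears once.
// [[Rcpp::export]]
IntegerMatrix cpp_crosslink_candidates(const NumericMatrix& pos,
                                       const IntegerVector& fiber_id,
                                       double radius) {
  const int n = pos.nrow();
  if (n == 0) return IntegerMatrix(0, 2);
  double xmin = pos(0, 0), ymin = pos(0, 1);
  for (int b = 0; b < n; ++b) {
    if (pos(b, 0) < xmin) xmin = pos(b, 0);
    if (pos(b, 1) < ymin) ymin = pos(b, 1);
  }
  const double r2 = radius * radius;
  const double inv = 1.0 / radius;
  std::unordered_map<long long, std::vector<int> > cells;
  std::vector<long long> key(n);
  for (int b = 0; b < n; ++b) {
    const long long cx = (long long)std::floor((pos(b, 0) - xmin) * inv);
    const long long cy = (long long)std::floor((pos(b, 1) - ymin) * inv);
    key[b] = (cx << 32) ^ (cy & 0xffffffffLL);
    cells[key[b]].push_back(b);
  }
  std::vector<int> out_i, out_j;
  for (int b = 0; b < n; ++b) {
    const long long cx = key[b] >> 32;
    const long long cy = (key[b] << 32) >> 32;
    for (long long dx = -1; dx <= 1; ++dx) {
      for (long long dy = -1; dy <= 1; ++dy) {
        const long long k = ((cx + dx) << 32) ^ ((cy + dy) & 0xffffffffLL);
        std::unordered_map<long long, std::vector<int> >::const_iterator it =
            cells.find(k);
        if (it == cells.end()) continue;
        const std::vector<int>& v = it->second;
        for (size_t q = 0; q < v.size(); ++q) {
          const int c = v[q];
          if (c <= b || fiber_id[c] == fiber_id[b]) continue;
          const double ddx = pos(b, 0) - pos(c, 0);
          const double ddy = pos(b, 1) - pos(c, 1);
          if (ddx * ddx + ddy * ddy <= r2) {
            out_i.push_back(b);
            out_j.push_back(c);
          }
        }
      }
    }
  }
  IntegerMatrix out(out_i.size(), 2);
  for (size_t q = 0; q < out_i.size(); ++q) {
    out(q, 0) = out_i[q];
    out(q, 1) = out_j[q];
  }
  return out;
}
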