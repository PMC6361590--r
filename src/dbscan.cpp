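#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Grid-accelerated DBSCAN on 2-D points. Cell width = eps, so all
// neighbours of a point lie in its 3x3 cell block. Neighbour counts include
// the point itself. Labels: 0 = noise, clusters numbered 1.. in order of
// discovery (deterministic in input order; border points attach to the
// first core cluster that reaches them).
static inline std::int64_t cell_key(std::int64_t ix, std::int64_t iy) {
  // collisions are harmless: candidates are always distance-checked
  return ix * 73856093LL + iy * 19349663LL;
}

// [[Rcpp::export(name = ".dbscan_cpp")]]
IntegerVector dbscan_cpp(NumericVector x, NumericVector y,
                         double eps, int min_pts) {
  const int n = x.size();
  IntegerVector labels(n, 0);
  if (n == 0) return labels;

  const double eps2 = eps * eps;
  std::unordered_map<std::int64_t, std::vector<int> > grid;
  grid.reserve(static_cast<size_t>(n) * 2);
  std::vector<std::int64_t> cix(n), ciy(n);
  for (int i = 0; i < n; ++i) {
    cix[i] = static_cast<std::int64_t>(std::floor(x[i] / eps));
    ciy[i] = static_cast<std::int64_t>(std::floor(y[i] / eps));
    grid[cell_key(cix[i], ciy[i])].push_back(i);
  }

  std::vector<int> nbr;
  auto region_query = [&](int i, std::vector<int> &out) {
    out.clear();
    for (std::int64_t dx = -1; dx <= 1; ++dx) {
      for (std::int64_t dy = -1; dy <= 1; ++dy) {
        auto it = grid.find(cell_key(cix[i] + dx, ciy[i] + dy));
        if (it == grid.end()) continue;
        for (int j : it->second) {
          const double ddx = x[i] - x[j], ddy = y[i] - y[j];
          if (ddx * ddx + ddy * ddy <= eps2) out.push_back(j);
        }
      }
    }
  };

  std::vector<char> visited(n, 0);
  std::vector<int> queue_, nbr2;
  int cluster = 0;
  for (int i = 0; i < n; ++i) {
    if (visited[i]) continue;
    visited[i] = 1;
    region_query(i, nbr);
    if (static_cast<int>(nbr.size()) < min_pts) continue;  // noise (for now)
    ++cluster;
    labels[i] = cluster;
    queue_.assign(nbr.begin(), nbr.end());
    for (size_t qi = 0; qi < queue_.size(); ++qi) {
      const int q = queue_[qi];
      if (labels[q] == 0) labels[q] = cluster;  // border or former noise
      if (!visited[q]) {
        visited[q] = 1;
        region_query(q, nbr2);
        if (static_cast<int>(nbr2.size()) >= min_pts) {
          queue_.insert(queue_.end(), nbr2.begin(), nbr2.end());
        }
      }
    }
  }
  return labels;
}
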