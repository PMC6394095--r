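#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// K distinct kernel-weighted neighbor candidates for every level: from
// level i (0-based), draw j = round(rnorm(i, sigma)) and reject draws that
// fall outside [0, n), equal i, or repeat an earlier draw, until K distinct
// values are collected. Uses R's RNG, so results are reproducible under
// set.seed(). Returns an n x K matrix of 0-based indices, or throws if the
// kernel cannot supply K distinct values within the try budget (callers
// should fall back to exact weighted sampling in that case).
// [[Rcpp::export]]
IntegerMatrix cpp_kernel_draws(int n, int K, double sigma) {
  if (K < 1 || K > n - 1) stop("K must lie in [1, n - 1]");
  IntegerMatrix out(n, K);
  std::vector<char> seen(n);
  const double max_tries = 4000.0 * K + 1e6;
  for (int i = 0; i < n; ++i) {
    std::fill(seen.begin(), seen.end(), 0);
    int got = 0;
    double tries = 0;
    while (got < K) {
      if (++tries > max_tries)
        stop("kernel rejection sampling stalled (K too large for sigma)");
      double z = i + norm_rand() * sigma;
      int j = (int)std::lround(z);
      if (j < 0 || j >= n || j == i || seen[j]) continue;
      seen[j] = 1;
      out(i, got++) = j;
    }
  }
  return out;
}

// Strict (degree-capped, then topped-up toward K-regular) symmetrization.
// Input: the n x K per-node proposal matrix (0-based). Proposed undirected
// edges are deduplicated, visited in random order and accepted while both
// endpoints are below degree K; remaining under-degree nodes are then
// paired with kernel-weighted rejection draws among other under-degree,
// non-adjacent nodes (a perfect K-regular completion may not exist; the
// few leftover deficits surface in the realized mean degree). Returns the
// edge list (i < j, 0-based). Uses R's RNG throughout.
// [[Rcpp::export]]
List cpp_strict_edges(IntegerMatrix draws0, int K, double sigma) {
  const int n = draws0.nrow();
  std::vector<std::vector<int>> adj(n);
  std::vector<int> deg(n, 0);

  std::vector<long long> keys;
  keys.reserve((size_t)n * draws0.ncol());
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < draws0.ncol(); ++c) {
      int j = draws0(i, c);
      int a = i < j ? i : j, b = i < j ? j : i;
      keys.push_back((long long)a * n + b);
    }
  std::sort(keys.begin(), keys.end());
  keys.erase(std::unique(keys.begin(), keys.end()), keys.end());

  const int m = (int)keys.size();
  std::vector<int> ord(m);
  for (int e = 0; e < m; ++e) ord[e] = e;
  for (int e = m - 1; e > 0; --e) {
    int r = (int)(unif_rand() * (e + 1));
    if (r > e) r = e;
    std::swap(ord[e], ord[r]);
  }

  for (int e = 0; e < m; ++e) {
    int a = (int)(keys[ord[e]] / n), b = (int)(keys[ord[e]] % n);
    if (deg[a] < K && deg[b] < K) {
      adj[a].push_back(b);
      adj[b].push_back(a);
      ++deg[a]; ++deg[b];
    }
  }

  auto is_adj = [&](int i, int j) {
    const std::vector<int> &v = adj[i];
    return std::find(v.begin(), v.end(), j) != v.end();
  };

  size_t prev_need = (size_t)n + 1;
  for (int pass = 0; pass < 25; ++pass) {
    std::vector<int> need;
    for (int i = 0; i < n; ++i) if (deg[i] < K) need.push_back(i);
    if (need.empty() || need.size() >= prev_need) break;
    prev_need = need.size();
    for (int e = (int)need.size() - 1; e > 0; --e) {
      int r = (int)(unif_rand() * (e + 1));
      if (r > e) r = e;
      std::swap(need[e], need[r]);
    }
    bool progress = false;
    for (int idx = 0; idx < (int)need.size(); ++idx) {
      int i = need[idx];
      double tries = 0;
      const double max_tries = 100.0 * K + 2000.0;
      while (deg[i] < K && tries < max_tries) {
        ++tries;
        double z = i + norm_rand() * sigma;
        int j = (int)std::lround(z);
        if (j < 0 || j >= n || j == i || deg[j] >= K || is_adj(i, j))
          continue;
        adj[i].push_back(j);
        adj[j].push_back(i);
        ++deg[i]; ++deg[j];
        progress = true;
      }
    }
    if (!progress) break;
  }

  int total = 0;
  for (int i = 0; i < n; ++i) total += deg[i];
  IntegerVector ai(total / 2), bj(total / 2);
  int c = 0;
  for (int i = 0; i < n; ++i)
    for (int j : adj[i]) if (i < j) { ai[c] = i; bj[c] = j; ++c; }
  return List::create(_["i"] = ai, _["j"] = bj);
}
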