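// Exact empirical Wasserstein-1 distance between two uniform empirical
// measures with Euclidean ground cost, solved as a transportation problem
// by successive shortest augmenting paths with node potentials (min-cost
// flow). Supplies/demands are scaled to integers (m per source point, n per
// target point, reduced by gcd) so the augmentation count is finite; the
// returned value divides the optimal integer-mass cost by n*m/g.

#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

static long long gcd_ll(long long a, long long b) {
  while (b) { long long t = a % b; a = b; b = t; }
  return a;
}

// [[Rcpp::export(name = ".ot_wasserstein")]]
double ot_wasserstein(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow(), d = A.ncol();
  if (B.ncol() != d) stop("dimension mismatch between the two sample sets");

  // Euclidean cost matrix, computed pairwise for accuracy.
  std::vector<double> C((size_t)n * m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = A(i, k) - B(j, k);
        s += diff * diff;
      }
      C[(size_t)i * m + j] = std::sqrt(s);
    }

  long long g = gcd_ll(n, m);
  long long supply_unit = m / g;   // mass per source point
  long long demand_unit = n / g;   // mass per target point
  long long total = (long long)n * (long long)(m / g); // total integer mass

  std::vector<long long> rs(n, supply_unit); // remaining supply
  std::vector<long long> rd(m, demand_unit); // remaining demand
  std::vector<long long> F((size_t)n * m, 0); // flow
  std::vector<double> pu(n, 0.0), pv(m, 0.0); // potentials

  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> dist_u(n), dist_v(m);
  std::vector<int> par_u(n), par_v(m); // parent sink of source / parent source of sink
  std::vector<char> done_u(n), done_v(m);

  long long remaining = total;
  long long guard = 4LL * (n + m) * (n + m) + 64;

  while (remaining > 0) {
    if (--guard < 0) stop("transport solver failed to converge");
    // Multi-source Dijkstra over the bipartite residual graph.
    for (int i = 0; i < n; ++i) {
      dist_u[i] = rs[i] > 0 ? 0.0 : INF;
      par_u[i] = -1; done_u[i] = 0;
    }
    for (int j = 0; j < m; ++j) { dist_v[j] = INF; par_v[j] = -1; done_v[j] = 0; }

    int best_sink = -1;
    while (true) {
      // pick unfinished node with smallest tentative distance
      double best = INF; int bi = -1; bool is_u = true;
      for (int i = 0; i < n; ++i)
        if (!done_u[i] && dist_u[i] < best) { best = dist_u[i]; bi = i; is_u = true; }
      for (int j = 0; j < m; ++j)
        if (!done_v[j] && dist_v[j] < best) { best = dist_v[j]; bi = j; is_u = false; }
      if (bi < 0) break;
      if (is_u) {
        done_u[bi] = 1;
        const size_t off = (size_t)bi * m;
        for (int j = 0; j < m; ++j) {
          if (done_v[j]) continue;
          double rc = C[off + j] - pu[bi] - pv[j]; // forward arc, rc >= 0
          if (rc < 0) rc = 0;                      // guard rounding
          double nd = dist_u[bi] + rc;
          if (nd < dist_v[j]) { dist_v[j] = nd; par_v[j] = bi; }
        }
      } else {
        done_v[bi] = 1;
        if (rd[bi] > 0) { best_sink = bi; break; } // shortest deficient sink reached
        for (int i = 0; i < n; ++i) {
          if (done_u[i] || F[(size_t)i * m + bi] <= 0) continue;
          double rc = -(C[(size_t)i * m + bi] - pu[i] - pv[bi]); // backward arc
          if (rc < 0) rc = 0;
          double nd = dist_v[bi] + rc;
          if (nd < dist_u[i]) { dist_u[i] = nd; par_u[i] = bi; }
        }
      }
    }
    if (best_sink < 0) stop("transport solver: no augmenting path (unbalanced problem)");

    const double dstar = dist_v[best_sink];
    // Johnson-style potential update (distances capped at dstar) keeps every
    // residual reduced cost nonnegative and tightens the shortest path.
    for (int i = 0; i < n; ++i) pu[i] -= std::min(dist_u[i], dstar);
    for (int j = 0; j < m; ++j) pv[j] += std::min(dist_v[j], dstar);
    // After the update the arcs on the shortest path are tight; augment.
    long long push = rd[best_sink];
    {
      int j = best_sink;
      while (true) {
        int i = par_v[j];
        if (F[(size_t)i * m + j] < 0) stop("transport solver: negative flow");
        if (par_u[i] < 0) { if (rs[i] < push) push = rs[i]; break; }
        int jprev = par_u[i];
        if (F[(size_t)i * m + jprev] < push) push = F[(size_t)i * m + jprev];
        j = jprev;
      }
    }
    {
      int j = best_sink;
      while (true) {
        int i = par_v[j];
        F[(size_t)i * m + j] += push;
        if (par_u[i] < 0) { rs[i] -= push; break; }
        int jprev = par_u[i];
        F[(size_t)i * m + jprev] -= push;
        j = jprev;
      }
    }
    rd[best_sink] -= push;
    remaining -= push;
  }

  double cost = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      if (F[(size_t)i * m + j] > 0)
        cost += (double)F[(size_t)i * m + j] * C[(size_t)i * m + j];
  return cost / (double)total;
}
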