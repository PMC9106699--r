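#include <Rcpp.h>
#include <queue>
#include <limits>
#include <vector>

using namespace Rcpp;

// Min-cost maximum-cardinality bipartite matching on a sparse edge list,
// by successive shortest augmenting paths with Johnson potentials
// (min-cost flow with a unit-capacity super source/sink). Each iteration
// finds the globally cheapest augmenting path from any unmatched treated
// node to any unmatched control node, so the final matching has maximum
// cardinality and, among those, minimum total cost.
//
// ei, ej: 0-based treated / control indices; ec: non-negative costs.
// Returns match_t (1-based control index per treated, 0 = unmatched).
// [[Rcpp::export]]
IntegerVector min_cost_max_matching(int nt, int nc,
                                    IntegerVector ei, IntegerVector ej,
                                    NumericVector ec) {
  std::vector<std::vector<std::pair<int, double> > > adj(nt);
  for (int k = 0; k < ei.size(); ++k)
    adj[ei[k]].push_back(std::make_pair(ej[k], ec[k]));

  std::vector<int> mt(nt, -1), mc(nc, -1);
  std::vector<double> pt(nt, 0.0), pc(nc, 0.0);
  const double INF = std::numeric_limits<double>::infinity();
  const int N = nt + nc;

  typedef std::pair<double, int> P;
  for (;;) {
    std::vector<double> dist(N, INF);
    std::vector<int> prev_t(nc, -1);
    std::vector<char> done(N, 0);
    std::priority_queue<P, std::vector<P>, std::greater<P> > pq;
    for (int t = 0; t < nt; ++t)
      if (mt[t] < 0) { dist[t] = 0.0; pq.push(std::make_pair(0.0, t)); }

    int best_c = -1;
    double best_d = INF;
    while (!pq.empty()) {
      double d = pq.top().first;
      int v = pq.top().second;
      pq.pop();
      if (done[v] || d > dist[v]) continue;
      done[v] = 1;
      if (v < nt) {
        for (size_t a = 0; a < adj[v].size(); ++a) {
          int c = adj[v][a].first;
          if (mt[v] == c) continue;          // saturated edge
          double rc = adj[v][a].second + pt[v] - pc[c];
          if (rc < 0) rc = 0;                // guard float noise
          double nd = d + rc;
          if (nd < dist[nt + c]) {
            dist[nt + c] = nd;
            prev_t[c] = v;
            pq.push(std::make_pair(nd, nt + c));
          }
        }
      } else {
        int c = v - nt;
        if (mc[c] < 0) { best_c = c; best_d = d; break; }
        int t = mc[c];                       // matched edge, backward, cost 0
        if (d < dist[t]) { dist[t] = d; pq.push(std::make_pair(d, t)); }
      }
    }
    if (best_c < 0) break;                   // no augmenting path left

    for (int t = 0; t < nt; ++t)
      if (dist[t] < INF) pt[t] += std::min(dist[t], best_d);
      else pt[t] += best_d;
    for (int c = 0; c < nc; ++c)
      if (dist[nt + c] < INF) pc[c] += std::min(dist[nt + c], best_d);
      else pc[c] += best_d;

    int c = best_c;
    while (c >= 0) {
      int t = prev_t[c];
      int next_c = mt[t];
      mt[t] = c;
      mc[c] = t;
      c = next_c;
    }
  }

  IntegerVector out(nt);
  for (int t = 0; t < nt; ++t) out[t] = mt[t] + 1;  // 1-based, 0 = unmatched
  return out;
}
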