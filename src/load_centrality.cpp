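#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Load centrality (Goh et al. traffic model): a unit packet travels from
// every node to every other node along shortest paths, splitting equally
// among the predecessors available at each hop. A node's load is the total
// transit mass, endpoints excluded, halved for undirected graphs and
// normalised by (n-1)(n-2)/2. On graphs with unique shortest paths (trees)
// this equals normalised betweenness.
//
// adj: 0-based adjacency list (list of integer vectors), undirected simple
// graph. Returns the normalised load per node.
// [[Rcpp::export]]
NumericVector load_centrality_cpp(List adj) {
  int n = adj.size();
  NumericVector load(n);
  if (n < 3) return load;

  std::vector< std::vector<int> > nbrs(n);
  for (int i = 0; i < n; ++i) nbrs[i] = as< std::vector<int> >(adj[i]);

  std::vector<int> dist(n), order(n);
  std::vector<double> between(n);

  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    int nord = 0;
    dist[s] = 0;
    order[nord++] = s;
    for (int qi = 0; qi < nord; ++qi) {   // BFS; order[] is nondecreasing in dist
      int v = order[qi];
      for (size_t j = 0; j < nbrs[v].size(); ++j) {
        int w = nbrs[v][j];
        if (dist[w] < 0) { dist[w] = dist[v] + 1; order[nord++] = w; }
      }
    }
    for (int qi = 0; qi < nord; ++qi) between[order[qi]] = 1.0;
    // farthest-first accumulation; packets at distance 1 are absorbed (the
    // only predecessor is the source itself, an endpoint)
    for (int qi = nord - 1; qi >= 0; --qi) {
      int v = order[qi];
      if (dist[v] <= 1) continue;
      int npred = 0;
      for (size_t j = 0; j < nbrs[v].size(); ++j)
        if (dist[nbrs[v][j]] == dist[v] - 1) ++npred;
      double share = between[v] / npred;
      for (size_t j = 0; j < nbrs[v].size(); ++j) {
        int w = nbrs[v][j];
        if (dist[w] == dist[v] - 1) between[w] += share;
      }
    }
    for (int qi = 1; qi < nord; ++qi) {
      int v = order[qi];
      load[v] += between[v] - 1.0;      // subtract the node's own packet
    }
  }
  double scale = 1.0 / ((double)(n - 1) * (double)(n - 2)); // ordered pairs
  for (int i = 0; i < n; ++i) load[i] *= scale;
  return load;
}
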