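#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------------------
// Exact transportation problem (discrete Wasserstein-1) by successive
// shortest augmenting paths on the bipartite residual graph.
//
// Supplies a (length m) and demands b (length n) are probability masses and
// must have equal totals; cost is the m x n ground-distance matrix.  Each
// augmentation finds a shortest residual path with Dijkstra under node
// potentials (Johnson reduction), so all reduced arc costs are nonnegative
// and the predecessor structure is a tree; every augmentation saturates a
// remaining supply, demand, or residual arc.  Exact for the LP optimum up
// to floating-point rounding; no entropic regularisation anywhere.
// ---------------------------------------------------------------------------
static double transport_ssp(const std::vector<double>& a,
                            const std::vector<double>& b,
                            const std::vector<double>& C, // row-major m x n
                            int m, int n,
                            std::vector<double>& flow) {
  const double EPS = 1e-13;
  std::vector<double> ra(a), rb(b);
  flow.assign((size_t)m * n, 0.0);
  double remaining = 0.0;
  for (double x : ra) remaining += x;

  int N = m + n;
  std::vector<double> pot(N, 0.0);
  typedef std::pair<double, int> Item;

  int guard = 0, max_aug = 10 * (m + n) + 20;
  while (remaining > 1e-12 && guard++ < max_aug) {
    std::vector<double> dist(N, INF);
    std::vector<int> prev(N, -1);
    std::priority_queue<Item, std::vector<Item>, std::greater<Item>> pq;
    for (int i = 0; i < m; ++i)
      if (ra[i] > EPS) { dist[i] = 0.0; pq.push({0.0, i}); }

    while (!pq.empty()) {
      Item it = pq.top(); pq.pop();
      double d = it.first; int u = it.second;
      if (d > dist[u]) continue;
      if (u < m) {
        // forward arcs u -> sink j (unlimited capacity)
        for (int j = 0; j < n; ++j) {
          double rc = C[(size_t)u * n + j] + pot[u] - pot[m + j];
          if (rc < 0) rc = 0; // rounding guard; true reduced costs are >= 0
          double nd = d + rc;
          if (nd < dist[m + j]) {
            dist[m + j] = nd; prev[m + j] = u; pq.push({nd, m + j});
          }
        }
      } else {
        // reverse arcs sink j -> source i (capacity = current flow)
        int j = u - m;
        for (int i = 0; i < m; ++i) {
          if (flow[(size_t)i * n + j] <= EPS) continue;
          double rc = -C[(size_t)i * n + j] + pot[u] - pot[i];
          if (rc < 0) rc = 0;
          double nd = d + rc;
          if (nd < dist[i]) {
            dist[i] = nd; prev[i] = u; pq.push({nd, i});
          }
        }
      }
    }

    // best reachable sink with remaining demand
    int t = -1;
    for (int j = 0; j < n; ++j)
      if (rb[j] > EPS && dist[m + j] < INF &&
          (t == -1 || dist[m + j] < dist[m + t]))
        t = j;
    if (t == -1) break; // numerically exhausted

    // update potentials (cap unreached nodes at the sink distance)
    double dt = dist[m + t];
    for (int v = 0; v < N; ++v)
      pot[v] += std::min(dist[v], dt);

    // trace path back, find bottleneck
    double amt = rb[t];
    int node = m + t;
    while (prev[node] != -1) {
      int p = prev[node];
      if (node >= m) {
        // forward arc p -> node: unlimited capacity
      } else {
        // reverse arc (p = m + j) -> node (= source i): limited by flow
        int j = p - m, i = node;
        amt = std::min(amt, flow[(size_t)i * n + j]);
      }
      node = p;
    }
    amt = std::min(amt, ra[node]); // node is the originating source
    if (amt <= EPS) break;

    // apply augmentation
    int cur = m + t;
    while (prev[cur] != -1) {
      int p = prev[cur];
      if (cur >= m) {
        flow[(size_t)p * n + (cur - m)] += amt;
      } else {
        flow[(size_t)cur * n + (p - m)] -= amt;
      }
      cur = p;
    }
    ra[cur] -= amt;
    rb[t] -= amt;
    remaining -= amt;
  }

  double total = 0.0;
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j)
      total += flow[(size_t)i * n + j] * C[(size_t)i * n + j];
  return total;
}

//' @noRd
// [[Rcpp::export]]
List cpp_transport(NumericVector supply, NumericVector demand,
                   NumericMatrix cost) {
  int m = supply.size(), n = demand.size();
  if (cost.nrow() != m || cost.ncol() != n)
    stop("cost matrix dimensions do not match the marginals");
  double sa = 0.0, sb = 0.0;
  for (int i = 0; i < m; ++i) sa += supply[i];
  for (int j = 0; j < n; ++j) sb += demand[j];
  if (std::fabs(sa - sb) > 1e-9)
    stop("infeasible marginals: mass mismatch of %g", std::fabs(sa - sb));

  std::vector<double> a(supply.begin(), supply.end());
  std::vector<double> b(demand.begin(), demand.end());
  std::vector<double> C((size_t)m * n);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j)
      C[(size_t)i * n + j] = cost(i, j);

  std::vector<double> flow;
  double total = transport_ssp(a, b, C, m, n, flow);

  NumericMatrix plan(m, n);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j)
      plan(i, j) = flow[(size_t)i * n + j];
  return List::create(_["cost"] = total, _["plan"] = plan);
}

// ---------------------------------------------------------------------------
// All-pairs shortest paths (Dijkstra, binary heap) on an undirected graph
// given as 1-based edge endpoints with positive per-edge costs.
// ---------------------------------------------------------------------------
static void dijkstra_row(int n, const std::vector<std::vector<int>>& adj,
                         const std::vector<std::vector<double>>& adj_cost,
                         int src, std::vector<double>& dist) {
  dist.assign(n, INF);
  dist[src] = 0.0;
  typedef std::pair<double, int> Item;
  std::priority_queue<Item, std::vector<Item>, std::greater<Item>> pq;
  pq.push({0.0, src});
  while (!pq.empty()) {
    Item it = pq.top(); pq.pop();
    double d = it.first; int u = it.second;
    if (d > dist[u]) continue;
    for (size_t k = 0; k < adj[u].size(); ++k) {
      int v = adj[u][k];
      double nd = d + adj_cost[u][k];
      if (nd < dist[v]) { dist[v] = nd; pq.push({nd, v}); }
    }
  }
}

//' @noRd
// [[Rcpp::export]]
NumericMatrix cpp_all_pairs_dijkstra(int n, IntegerVector ei, IntegerVector ej,
                                     NumericVector cost) {
  int ne = ei.size();
  std::vector<std::vector<int>> adj(n);
  std::vector<std::vector<double>> adj_cost(n);
  for (int e = 0; e < ne; ++e) {
    int u = ei[e] - 1, v = ej[e] - 1;
    adj[u].push_back(v); adj_cost[u].push_back(cost[e]);
    adj[v].push_back(u); adj_cost[v].push_back(cost[e]);
  }
  NumericMatrix D(n, n);
  std::vector<double> row;
  for (int s = 0; s < n; ++s) {
    dijkstra_row(n, adj, adj_cost, s, row);
    for (int t = 0; t < n; ++t) D(s, t) = row[t];
  }
  return D;
}

// ---------------------------------------------------------------------------
// Fused per-sample curvature profile.
//
// Given the topology (1-based edge list) and positive node weights w, computes
// the mass-action chain p_jk = w_k / sum_{l ~ j} w_l, symmetrised edge
// interaction weights w_uv = (p_uv + p_vu)/2, the weighted hop metric
// (per-edge length 1/w_uv, Dijkstra on the full graph), exact W1 between the
// one-step neighbourhood measures of each edge's endpoints, the per-edge
// Ollivier-Ricci curvature kappa = 1 - W1/d, the closed-form stationary
// distribution pi_j = w_j * sum_{j ~ k} w_k / Z, the stationary-weighted
// nodal scalar curvature and the network total.
// ---------------------------------------------------------------------------
//' @noRd
// [[Rcpp::export]]
List cpp_curvature_profile(int n, IntegerVector ei, IntegerVector ej,
                           NumericVector w) {
  int ne = ei.size();
  std::vector<std::vector<int>> nbr(n);
  for (int e = 0; e < ne; ++e) {
    int u = ei[e] - 1, v = ej[e] - 1;
    nbr[u].push_back(v);
    nbr[v].push_back(u);
  }

  std::vector<double> S(n, 0.0); // sum of neighbour weights
  for (int j = 0; j < n; ++j) {
    for (int k : nbr[j]) S[j] += w[k];
    if (S[j] <= 0.0) stop("isolated node in curvature computation");
  }

  // symmetrised edge interaction weights and metric edge costs
  NumericVector edge_w(ne), edge_cost(ne);
  for (int e = 0; e < ne; ++e) {
    int u = ei[e] - 1, v = ej[e] - 1;
    double puv = w[v] / S[u], pvu = w[u] / S[v];
    edge_w[e] = 0.5 * (puv + pvu);
    edge_cost[e] = 1.0 / edge_w[e];
  }

  NumericMatrix D = cpp_all_pairs_dijkstra(n, ei, ej, edge_cost);

  NumericVector kappa_e(ne), w1_e(ne), d_e(ne);
  std::vector<double> a, b, C, flow;
  for (int e = 0; e < ne; ++e) {
    int u = ei[e] - 1, v = ej[e] - 1;
    const std::vector<int>& su = nbr[u];
    const std::vector<int>& sv = nbr[v];
    int m = su.size(), k = sv.size();
    a.resize(m); b.resize(k); C.resize((size_t)m * k);
    for (int i = 0; i < m; ++i) a[i] = w[su[i]] / S[u];
    for (int j = 0; j < k; ++j) b[j] = w[sv[j]] / S[v];
    for (int i = 0; i < m; ++i)
      for (int j = 0; j < k; ++j)
        C[(size_t)i * k + j] = D(su[i], sv[j]);
    double W1 = transport_ssp(a, b, C, m, k, flow);
    double d = D(u, v);
    w1_e[e] = W1;
    d_e[e] = d;
    kappa_e[e] = 1.0 - W1 / d;
  }

  // closed-form stationary distribution
  NumericVector pi(n);
  double Z = 0.0;
  for (int j = 0; j < n; ++j) { pi[j] = w[j] * S[j]; Z += pi[j]; }
  for (int j = 0; j < n; ++j) pi[j] /= Z;

  // nodal scalar curvature and total
  NumericVector kappa_node(n);
  for (int e = 0; e < ne; ++e) {
    kappa_node[ei[e] - 1] += kappa_e[e];
    kappa_node[ej[e] - 1] += kappa_e[e];
  }
  double total = 0.0;
  for (int j = 0; j < n; ++j) {
    kappa_node[j] *= pi[j];
    total += kappa_node[j];
  }

  return List::create(
    _["edge_kappa"] = kappa_e,
    _["edge_w1"] = w1_e,
    _["edge_distance"] = d_e,
    _["edge_weight"] = edge_w,
    _["pi"] = pi,
    _["node_kappa"] = kappa_node,
    _["total"] = total);
}
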