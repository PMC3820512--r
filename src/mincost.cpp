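#include <Rcpp.h>
#include <vector>
#include <deque>
#include <limits>
#include <cmath>
using namespace Rcpp;

// Min-cost flow with a free flow value: the source-reward term of the
// objective is folded by the caller into (negative) costs on the arcs
// leaving the auxiliary source, so the optimum is the cheapest circulation
// and is found by augmenting along the cheapest residual S->T path while
// that path has strictly negative total cost.
//
// Residual arcs are stored in pairs: arc 2k is the forward copy of input
// arc k, arc 2k+1 its reverse; (e ^ 1) flips direction.

namespace {

struct Residual {
  int n;
  std::vector<int> head, nxt, to;
  std::vector<double> cap, cost;
  explicit Residual(int n_) : n(n_), head(n_, -1) {}
  void add(int u, int v, double c, double w) {
    to.push_back(v);
    cap.push_back(c);
    cost.push_back(w);
    nxt.push_back(head[u]);
    head[u] = static_cast<int>(to.size()) - 1;
  }
};

// Shortest path by SPFA (handles the negative source-arc costs; no
// negative cycles arise during successive shortest path augmentation).
void spfa(const Residual& g, int s, std::vector<double>& dist,
          std::vector<int>& parc, double captol) {
  const double INF = std::numeric_limits<double>::infinity();
  dist.assign(g.n, INF);
  parc.assign(g.n, -1);
  std::vector<char> inq(g.n, 0);
  std::deque<int> q;
  dist[s] = 0.0;
  q.push_back(s);
  inq[s] = 1;
  while (!q.empty()) {
    int u = q.front();
    q.pop_front();
    inq[u] = 0;
    for (int e = g.head[u]; e != -1; e = g.nxt[e]) {
      if (g.cap[e] <= captol) continue;
      int v = g.to[e];
      double nd = dist[u] + g.cost[e];
      if (nd < dist[v] - 1e-15) {
        dist[v] = nd;
        parc[v] = e;
        if (!inq[v]) {
          inq[v] = 1;
          if (!q.empty() && nd < dist[q.front()])
            q.push_front(v);
          else
            q.push_back(v);
        }
      }
    }
  }
}

}  // namespace

// [[Rcpp::export]]
List mcf_solve_cpp(int n, IntegerVector from, IntegerVector to,
                   NumericVector cap, NumericVector cost, int s, int t,
                   double tol = 1e-9, int max_aug = 200000) {
  int m = from.size();
  Residual g(n);
  for (int i = 0; i < m; ++i) {
    g.add(from[i] - 1, to[i] - 1, cap[i], cost[i]);
    g.add(to[i] - 1, from[i] - 1, 0.0, -cost[i]);
  }
  int s0 = s - 1, t0 = t - 1;
  std::vector<double> dist;
  std::vector<int> parc;
  int naug = 0;
  while (naug < max_aug) {
    spfa(g, s0, dist, parc, tol);
    if (!(dist[t0] < -tol)) break;
    double b = std::numeric_limits<double>::infinity();
    for (int v = t0; v != s0;) {
      int e = parc[v];
      b = std::min(b, g.cap[e]);
      v = g.to[e ^ 1];
    }
    for (int v = t0; v != s0;) {
      int e = parc[v];
      g.cap[e] -= b;
      g.cap[e ^ 1] += b;
      v = g.to[e ^ 1];
    }
    ++naug;
  }
  if (naug >= max_aug) stop("minimum-cost flow failed to converge");

  // The implicit zero-cost T->S return arc closes the circulation; at
  // optimality it carries the total flow. Adding its residual pair before
  // the final potential pass makes the potentials valid for
  // total-flow-changing objective-preserving reroutes as well.
  double total = 0.0;
  for (int i = 0; i < m; ++i) {
    if (from[i] - 1 == s0) total += g.cap[2 * i + 1];
  }
  double big = total;
  for (int i = 0; i < m; ++i) big += cap[i];
  g.add(t0, s0, big + 1.0, 0.0);
  g.add(s0, t0, total, 0.0);

  // Dual feasible potentials: Bellman-Ford from a virtual root joined to
  // every node with a zero-cost arc, run over the residual graph. At
  // optimality there is no negative residual cycle, so this converges and
  // yields cost + pot[u] - pot[v] >= 0 on every residual arc.
  std::vector<double> pot(n, 0.0);
  for (int it = 0; it < n + 1; ++it) {
    bool changed = false;
    for (int e = 0; e < static_cast<int>(g.to.size()); ++e) {
      if (g.cap[e] <= tol) continue;
      int u = g.to[e ^ 1], v = g.to[e];
      if (pot[u] + g.cost[e] < pot[v] - 1e-12) {
        pot[v] = pot[u] + g.cost[e];
        changed = true;
      }
    }
    if (!changed) break;
  }

  NumericVector flow(m);
  double obj = 0.0;
  for (int i = 0; i < m; ++i) {
    double f = g.cap[2 * i + 1];
    if (f < tol) f = 0.0;
    flow[i] = f;
    obj += f * cost[i];
  }
  return List::create(_["flow"] = flow, _["objective"] = obj,
                      _["potential"] = NumericVector(pot.begin(), pot.end()),
                      _["augmentations"] = naug);
}
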