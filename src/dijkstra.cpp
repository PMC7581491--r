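// Dijkstra shortest-path boundary extraction through a boundary-probability
// map.  Vertices are the pixels of the H x W map plus one dummy column on
// each side whose vertices behave as probability-1 pixels and are connected
// vertically at zero cost, so the corner-to-corner path can enter and leave
// the map at any row.  Every vertex is connected to its three rightmost
// neighbours (horizontal, diagonal up, diagonal down); edge weight
//   w(s,d) = 2 - (p_s + p_d)        (mode 0, default)
//   w(s,d) = 2 - p_s + p_d         (mode 1, literal variant)
// Ties are broken deterministically: the priority queue orders by
// (cost, column, row) and an equal-cost relaxation replaces the predecessor
// only for a preferred move type (dummy-vertical < horizontal < diagonal-up
// < diagonal-down).

#include <Rcpp.h>
#include <queue>
#include <tuple>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_dijkstra_boundary(NumericMatrix prob, int mode) {
  const int H = prob.nrow(), W = prob.ncol();
  const int Wt = W + 2;                     // with dummy columns
  const int NV = H * Wt;
  auto vid = [H](int r, int c) { return r + H * c; };
  std::vector<double> dist(NV, R_PosInf);
  std::vector<int> pred(NV, -1), prio(NV, 100);
  std::vector<bool> done(NV, false);

  auto pval = [&](int r, int c) -> double {  // c in dummy coords
    if (c == 0 || c == Wt - 1) return 1.0;
    return prob(r, c - 1);
  };
  auto weight = [&](double ps, double pd) -> double {
    return (mode == 0) ? 2.0 - (ps + pd) : 2.0 - ps + pd;
  };

  typedef std::tuple<double, int, int> QE;   // (cost, col, row)
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > q;
  const int start = vid(0, 0), end = vid(H - 1, Wt - 1);
  dist[start] = 0.0;
  q.push(QE(0.0, 0, 0));

  while (!q.empty()) {
    QE top = q.top(); q.pop();
    const double d = std::get<0>(top);
    const int c = std::get<1>(top), r = std::get<2>(top);
    const int u = vid(r, c);
    if (done[u] || d > dist[u]) continue;
    done[u] = true;
    if (u == end) break;
    const double ps = pval(r, c);

    // neighbour list: (dr, dc, move priority)
    // rightward moves exist for c < Wt-1; vertical moves only inside dummies
    struct Mv { int dr, dc, pr; };
    Mv moves[5];
    int nm = 0;
    if (c < Wt - 1) {
      moves[nm++] = Mv{ 0, 1, 1};
      moves[nm++] = Mv{-1, 1, 2};
      moves[nm++] = Mv{ 1, 1, 3};
    }
    if (c == 0 || c == Wt - 1) {
      moves[nm++] = Mv{-1, 0, 0};
      moves[nm++] = Mv{ 1, 0, 0};
    }
    for (int m = 0; m < nm; ++m) {
      const int rr = r + moves[m].dr, cc = c + moves[m].dc;
      if (rr < 0 || rr >= H) continue;
      const int v = vid(rr, cc);
      if (done[v]) continue;
      const double w = weight(ps, pval(rr, cc));
      const double nd = d + w;
      if (nd < dist[v] - 1e-12) {
        dist[v] = nd;
        pred[v] = u;
        prio[v] = moves[m].pr;
        q.push(QE(nd, cc, rr));
      } else if (std::abs(nd - dist[v]) <= 1e-12 && moves[m].pr < prio[v]) {
        pred[v] = u;
        prio[v] = moves[m].pr;
      }
    }
  }

  if (!R_finite(dist[end])) stop("no path found (corrupt edge map?)");

  // walk back; record the row of the path at each real column (take the
  // first row encountered per column when the path is vertical in dummies —
  // real columns always have exactly one path vertex)
  std::vector<int> rows(W, -1);
  for (int v = end; v != -1; v = pred[v]) {
    const int c = v / H, r = v % H;
    if (c >= 1 && c <= W) rows[c - 1] = r;
  }
  IntegerVector out(W);
  for (int i = 0; i < W; ++i) out[i] = rows[i];
  return List::create(_["rows"] = out, _["cost"] = dist[end]);
}
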