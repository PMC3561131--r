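#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Multi-source Dijkstra on a raster cost surface. Cell values are the time
// (seconds) needed to traverse one cell; the cost of a move between adjacent
// cells a -> b is (t_a + t_b)/2 * k with k = 1 for cardinal moves and
// sqrt(2) for diagonal moves (8-connected). NA cells are impassable.
// Returns the minimum accumulated time from the nearest source, NA where
// unreachable.

// [[Rcpp::export]]
NumericMatrix accumulate_time_cpp(NumericMatrix cost, IntegerMatrix sources) {
  const int nr = cost.nrow(), nc = cost.ncol();
  const double SQRT2 = std::sqrt(2.0);
  NumericMatrix dist(nr, nc);
  std::fill(dist.begin(), dist.end(), R_PosInf);

  typedef std::pair<double, int> Node;  // (distance, flat index r + c*nr)
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;

  if (sources.nrow() == 0) stop("no source cells");
  for (int s = 0; s < sources.nrow(); ++s) {
    int r = sources(s, 0) - 1, c = sources(s, 1) - 1;
    if (r < 0 || r >= nr || c < 0 || c >= nc)
      stop("source %d lies outside the grid", s + 1);
    if (NumericMatrix::is_na(cost(r, c)))
      continue;  // a source on an impassable cell reaches nothing
    dist(r, c) = 0.0;
    pq.push(Node(0.0, r + c * nr));
  }

  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const double kk[8] = {SQRT2, 1, SQRT2, 1, 1, SQRT2, 1, SQRT2};

  while (!pq.empty()) {
    Node top = pq.top(); pq.pop();
    double d = top.first;
    int idx = top.second, r = idx % nr, c = idx / nr;
    if (d > dist(r, c)) continue;
    double tc = cost(r, c);
    for (int m = 0; m < 8; ++m) {
      int r2 = r + dr[m], c2 = c + dc[m];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (NumericMatrix::is_na(cost(r2, c2))) continue;
      double nd = d + 0.5 * (tc + cost(r2, c2)) * kk[m];
      if (nd < dist(r2, c2)) {
        dist(r2, c2) = nd;
        pq.push(Node(nd, r2 + c2 * nr));
      }
    }
  }

  for (int i = 0; i < nr * nc; ++i)
    if (dist[i] == R_PosInf) dist[i] = NA_REAL;
  return dist;
}
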