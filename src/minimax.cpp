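#include <Rcpp.h>
#include <queue>
#include <algorithm>
using namespace Rcpp;

// Cells are addressed as 0-based linear indices into an nrow x ncol grid
// (column-major, matching R matrices). Connectivity is 8-neighbour.
// Masked cells carry NA energy and are impassable.

static inline int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// Lowest level at which `start` and `end` become connected through cells of
// energy <= level: the minimax (bottleneck) value over all grid paths.
// [[Rcpp::export]]
double cpp_minimax_bottleneck(NumericMatrix energy, int start, int end) {
  const int nr = energy.nrow(), nc = energy.ncol(), n = nr * nc;
  if (start < 0 || start >= n || end < 0 || end >= n)
    stop("start/end cell out of range");
  std::vector<int> order;
  order.reserve(n);
  for (int i = 0; i < n; ++i)
    if (!NumericMatrix::is_na(energy[i])) order.push_back(i);
  std::stable_sort(order.begin(), order.end(), [&](int a, int b) {
    return energy[a] < energy[b];
  });
  std::vector<int> parent(n);
  std::vector<char> added(n, 0);
  for (int i = 0; i < n; ++i) parent[i] = i;
  for (size_t k = 0; k < order.size(); ++k) {
    const int i = order[k];
    added[i] = 1;
    const int r = i % nr, c = i / nr;
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        if (dr == 0 && dc == 0) continue;
        const int rr = r + dr, cc = c + dc;
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        const int j = rr + cc * nr;
        if (added[j]) {
          const int ri = uf_find(parent, i), rj = uf_find(parent, j);
          if (ri != rj) parent[ri] = rj;
        }
      }
    }
    if (added[start] && added[end] &&
        uf_find(parent, start) == uf_find(parent, end))
      return energy[i];
  }
  return NA_REAL;  // disconnected
}

struct PathKey {
  double bneck, sum;
  int idx;
};
struct PathKeyCmp {
  bool operator()(const PathKey &a, const PathKey &b) const {
    if (a.bneck != b.bneck) return a.bneck > b.bneck;
    if (a.sum != b.sum) return a.sum > b.sum;
    return a.idx > b.idx;
  }
};

// Dijkstra with lexicographic key (path max, path sum, cell index); energies
// are shifted to be non-negative internally so the sum tie-break is
// label-setting. Returns 1-based linear cell indices from start to end.
// [[Rcpp::export]]
IntegerVector cpp_minimax_path(NumericMatrix energy, int start, int end) {
  const int nr = energy.nrow(), nc = energy.ncol(), n = nr * nc;
  if (start < 0 || start >= n || end < 0 || end >= n)
    stop("start/end cell out of range");
  if (NumericMatrix::is_na(energy[start]) || NumericMatrix::is_na(energy[end]))
    stop("start or end cell is masked");
  double emin = R_PosInf;
  for (int i = 0; i < n; ++i)
    if (!NumericMatrix::is_na(energy[i]) && energy[i] < emin) emin = energy[i];
  std::vector<double> bneck(n, R_PosInf), psum(n, R_PosInf);
  std::vector<int> pred(n, -1);
  std::vector<char> done(n, 0);
  std::priority_queue<PathKey, std::vector<PathKey>, PathKeyCmp> pq;
  bneck[start] = energy[start] - emin;
  psum[start] = energy[start] - emin;
  pq.push({bneck[start], psum[start], start});
  while (!pq.empty()) {
    PathKey top = pq.top();
    pq.pop();
    const int i = top.idx;
    if (done[i]) continue;
    done[i] = 1;
    if (i == end) break;
    const int r = i % nr, c = i / nr;
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        if (dr == 0 && dc == 0) continue;
        const int rr = r + dr, cc = c + dc;
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        const int j = rr + cc * nr;
        if (done[j] || NumericMatrix::is_na(energy[j])) continue;
        const double e = energy[j] - emin;
        const double nb = std::max(bneck[i], e);
        const double ns = psum[i] + e;
        if (nb < bneck[j] || (nb == bneck[j] && ns < psum[j])) {
          bneck[j] = nb;
          psum[j] = ns;
          pred[j] = i;
          pq.push({nb, ns, j});
        }
      }
    }
  }
  if (!done[end]) return IntegerVector(0);  // disconnected
  std::vector<int> rev;
  for (int i = end; i != -1; i = pred[i]) rev.push_back(i + 1);
  std::reverse(rev.begin(), rev.end());
  return wrap(rev);
}
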