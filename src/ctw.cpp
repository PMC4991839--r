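#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Context-tree weighting over an m-ary alphabet with Krichevsky-Trofimov
// estimators at every node. The weighted probability at each node follows
//   P_w = 1/2 P_e + 1/2 prod_children P_w   (internal nodes)
//   P_w = P_e                               (depth-D leaves)
// updated sequentially in the log domain along the context path of each
// symbol. Entropy rate = -log2 P_w(root) / (number of coded symbols).

namespace {

struct CtwTree {
  int m, D;
  // flat node storage
  std::vector<int> counts;       // m per node
  std::vector<int> children;     // m per node, -1 = absent
  std::vector<double> log_pe, log_pw, log_prod;
  explicit CtwTree(int m_, int D_) : m(m_), D(D_) { new_node(); }
  int new_node() {
    int id = (int)log_pe.size();
    counts.insert(counts.end(), m, 0);
    children.insert(children.end(), m, -1);
    log_pe.push_back(0.0);
    log_pw.push_back(0.0);
    log_prod.push_back(0.0);
    return id;
  }
  int child(int node, int sym) {
    int c = children[(size_t)node * m + sym];
    if (c < 0) {
      c = new_node();
      children[(size_t)node * m + sym] = c;
    }
    return c;
  }
  // KT increment for observing `sym` at `node`
  double kt_update(int node, int sym) {
    int* cnt = &counts[(size_t)node * m];
    int total = 0;
    for (int k = 0; k < m; ++k) total += cnt[k];
    double inc = std::log((cnt[sym] + 0.5) / (total + 0.5 * m));
    cnt[sym] += 1;
    log_pe[node] += inc;
    return inc;
  }
};

inline double log_add(double la, double lb) {
  if (la < lb) std::swap(la, lb);
  return la + std::log1p(std::exp(lb - la));
}

} // namespace

// x: symbols in 0..m-1; the first D symbols only seed the context.
// Returns the entropy rate in bits per symbol.
// [[Rcpp::export]]
double ctw_entropy_cpp(IntegerVector x, int D, int m) {
  int n = x.size();
  if (n <= D) stop("sequence shorter than context depth");
  for (int i = 0; i < n; ++i)
    if (x[i] < 0 || x[i] >= m) stop("symbol out of alphabet range");
  CtwTree tree(m, D);
  std::vector<int> path(D + 1);
  const double log_half = std::log(0.5);
  for (int t = D; t < n; ++t) {
    int sym = x[t];
    path[0] = 0;
    for (int d = 1; d <= D; ++d)
      path[d] = tree.child(path[d - 1], x[t - d]);
    // leaf
    int leaf = path[D];
    tree.kt_update(leaf, sym);
    double old_pw = tree.log_pw[leaf];
    tree.log_pw[leaf] = tree.log_pe[leaf];
    double delta = tree.log_pw[leaf] - old_pw;
    // propagate to root
    for (int d = D - 1; d >= 0; --d) {
      int nd = path[d];
      tree.kt_update(nd, sym);
      tree.log_prod[nd] += delta;
      double old = tree.log_pw[nd];
      tree.log_pw[nd] = log_add(log_half + tree.log_pe[nd],
                                log_half + tree.log_prod[nd]);
      delta = tree.log_pw[nd] - old;
    }
  }
  return -tree.log_pw[0] / ((n - D) * std::log(2.0));
}
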