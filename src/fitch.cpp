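#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Fitch parsimony length of a tree supplied as an undirected edge list.
//
// Node ids <= n_tip are leaves whose character-state sets sit in `enc`
// (row i = leaf i); larger ids are internal nodes of degree 3.  The tree is
// traversed from `root`, which must be a leaf present in the tree: rooting an
// unrooted binary tree along a pendant edge leaves the Fitch length unchanged,
// so a single leaf-rooted pass scores the unrooted topology exactly.
//
// enc holds one bitmask per (leaf, character): bit k set = state k allowed.
// Missing data is encoded upstream as the full observed-state mask.
//
// Returns the weighted total and, optionally, raw per-character step counts.
// [[Rcpp::export]]
List fitch_score_cpp(IntegerMatrix edge, int n_tip, int root,
                     IntegerMatrix enc, NumericVector weights,
                     bool per_char = false) {
  const int n_edge = edge.nrow();
  const int n_char = enc.ncol();
  int n_node = 0;
  for (int i = 0; i < n_edge; ++i) {
    if (edge(i, 0) > n_node) n_node = edge(i, 0);
    if (edge(i, 1) > n_node) n_node = edge(i, 1);
  }
  // adjacency (1-based ids)
  std::vector<std::vector<int> > adj(n_node + 1);
  for (int i = 0; i < n_edge; ++i) {
    adj[edge(i, 0)].push_back(edge(i, 1));
    adj[edge(i, 1)].push_back(edge(i, 0));
  }
  if (root < 1 || root > n_tip || adj[root].empty())
    stop("root must be a leaf present in the tree");

  // iterative DFS from `root`: build postorder and parent pointers
  std::vector<int> parent(n_node + 1, 0), post;
  post.reserve(n_node);
  std::vector<int> stack;
  stack.push_back(root);
  parent[root] = -1;
  std::vector<int> order;
  order.reserve(n_node);
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    order.push_back(v);
    for (size_t k = 0; k < adj[v].size(); ++k) {
      int w = adj[v][k];
      if (w != parent[v]) {
        parent[w] = v;
        stack.push_back(w);
      }
    }
  }
  // reverse preorder = a valid postorder (children before parents)
  post.assign(order.rbegin(), order.rend());

  // state sets: n_node x n_char bitmasks
  std::vector<int> set((size_t)(n_node + 1) * n_char, 0);
  std::vector<double> steps(n_char, 0.0);
  std::vector<int> nkid(n_node + 1, 0);

  for (size_t idx = 0; idx < post.size(); ++idx) {
    int v = post[idx];
    int* sv = &set[(size_t)v * n_char];
    if (v <= n_tip) {
      for (int c = 0; c < n_char; ++c) sv[c] = enc(v - 1, c);
    }
    // combine children (leaves other than the root have none; the root leaf
    // combines its own observed set with its single child's set)
    for (size_t k = 0; k < adj[v].size(); ++k) {
      int w = adj[v][k];
      if (w == parent[v]) continue;
      const int* sw = &set[(size_t)w * n_char];
      if (v > n_tip && nkid[v] == 0) {
        for (int c = 0; c < n_char; ++c) sv[c] = sw[c];
      } else {
        for (int c = 0; c < n_char; ++c) {
          int inter = sv[c] & sw[c];
          if (inter) {
            sv[c] = inter;
          } else {
            sv[c] = sv[c] | sw[c];
            steps[c] += 1.0;
          }
        }
      }
      nkid[v] += 1;
    }
  }

  double total = 0.0;
  for (int c = 0; c < n_char; ++c) total += steps[c] * weights[c];

  if (per_char) {
    return List::create(_["total"] = total,
                        _["per_char"] = NumericVector(steps.begin(), steps.end()));
  }
  return List::create(_["total"] = total);
}
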