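#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// k-shell decomposition on out-degree: peel nodes whose out-degree within the
// surviving subgraph is < k, for k = 1, 2, ...; a node's index is the largest
// k at which it survives (nodes removed during the k = 1 sweep get 0).
// Removing a node lowers the out-degree of its in-neighbours, so peeling walks
// the reversed adjacency. O(V + E) amortized per k level.
// [[Rcpp::export]]
IntegerVector k_shell_out_cpp(int n, IntegerVector pre, IntegerVector post) {
  int m = pre.size();
  std::vector<int> outdeg(n, 0);
  std::vector<int> in_off(n + 1, 0), in_nbr(m);
  for (int e = 0; e < m; ++e) {
    outdeg[pre[e] - 1]++;
    in_off[post[e] - 1 + 1]++;
  }
  for (int v = 0; v < n; ++v) in_off[v + 1] += in_off[v];
  std::vector<int> cur(in_off.begin(), in_off.end() - 1);
  for (int e = 0; e < m; ++e) in_nbr[cur[post[e] - 1]++] = pre[e] - 1;

  IntegerVector shell(n);
  std::vector<char> alive(n, 1);
  std::vector<int> stack;
  int n_alive = n;
  for (int k = 1; n_alive > 0; ++k) {
    for (int v = 0; v < n; ++v)
      if (alive[v] && outdeg[v] < k) stack.push_back(v);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      if (!alive[v]) continue;
      alive[v] = 0; n_alive--;
      shell[v] = k - 1;
      for (int idx = in_off[v]; idx < in_off[v + 1]; ++idx) {
        int u = in_nbr[idx];
        if (alive[u] && --outdeg[u] < k) stack.push_back(u);
      }
    }
  }
  return shell;
}
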