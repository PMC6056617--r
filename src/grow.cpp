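#include <Rcpp.h>
using namespace Rcpp;

// Growing-algorithm cluster sizes for a chunk of centre voxels.
//
// conn: n_mask x m logical matrix; column c flags the voxels whose
//       correlation with centre c exceeds the threshold (self included).
// centers: 0-based mask-order index of each column's centre voxel.
// ptr/nbr: CSR spatial neighbor graph over mask voxels (0-based ptr,
//          1-based neighbor ids as produced by mask_neighbor_graph).
// Returns |S| - 1 per centre: the grown cluster size excluding the centre.
// [[Rcpp::export]]
IntegerVector grow_counts_cpp(LogicalMatrix conn, IntegerVector centers,
                              IntegerVector ptr, IntegerVector nbr) {
  const int n = conn.nrow(), m = conn.ncol();
  IntegerVector out(m);
  std::vector<char> inset(n, 0);
  std::vector<int> stack, touched;
  stack.reserve(256); touched.reserve(256);
  for (int c = 0; c < m; ++c) {
    const int c0 = centers[c];
    int size = 1;
    inset[c0] = 1;
    stack.clear(); touched.clear();
    stack.push_back(c0); touched.push_back(c0);
    while (!stack.empty()) {
      const int v = stack.back(); stack.pop_back();
      for (int e = ptr[v]; e < ptr[v + 1]; ++e) {
        const int w = nbr[e] - 1;          // nbr is 1-based
        if (!inset[w] && conn(w, c)) {
          inset[w] = 1;
          ++size;
          stack.push_back(w); touched.push_back(w);
        }
      }
    }
    for (size_t i = 0; i < touched.size(); ++i) inset[touched[i]] = 0;
    out[c] = size - 1;
  }
  return out;
}

// Connected-component labels for a subset of mask voxels.
//
// active: 1-based mask-order ids of the suprathreshold voxels.
// ptr/nbr: CSR neighbor graph over all mask voxels (as above).
// Returns a label (1..n_components) per active voxel, in input order.
// [[Rcpp::export]]
IntegerVector label_components_cpp(IntegerVector active, IntegerVector ptr,
                                   IntegerVector nbr, int n_mask) {
  const int m = active.size();
  std::vector<int> lab(n_mask, 0);     // 0 = inactive/unlabeled
  std::vector<char> act(n_mask, 0);
  for (int i = 0; i < m; ++i) act[active[i] - 1] = 1;
  int next = 0;
  std::vector<int> stack;
  for (int i = 0; i < m; ++i) {
    const int s = active[i] - 1;
    if (lab[s]) continue;
    lab[s] = ++next;
    stack.clear(); stack.push_back(s);
    while (!stack.empty()) {
      const int v = stack.back(); stack.pop_back();
      for (int e = ptr[v]; e < ptr[v + 1]; ++e) {
        const int w = nbr[e] - 1;
        if (act[w] && !lab[w]) { lab[w] = next; stack.push_back(w); }
      }
    }
  }
  IntegerVector out(m);
  for (int i = 0; i < m; ++i) out[i] = lab[active[i] - 1];
  return out;
}
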