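#include <Rcpp.h>
using namespace Rcpp;

// Two-pass union-find connected-component labeling on a logical image.
// fg is column-major (R matrix layout), nrow x ncol. connectivity is 4 or 8.
// Returns integer labels (0 = background); labels are compacted but carry no
// ordering guarantee beyond first-touch raster order of the scan.

static int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]]; // path halving
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int> &parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector fg, int nrow, int ncol,
                                   int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int n = nrow * ncol;
  IntegerVector labels(n, 0);
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;

  // first pass: union each foreground pixel with already-scanned neighbours
  for (int c = 0; c < ncol; ++c) {
    for (int r = 0; r < nrow; ++r) {
      const int i = c * nrow + r;
      if (!fg[i]) continue;
      if (r > 0 && fg[i - 1]) uf_union(parent, i, i - 1);           // up
      if (c > 0 && fg[i - nrow]) uf_union(parent, i, i - nrow);     // left
      if (connectivity == 8) {
        if (r > 0 && c > 0 && fg[i - nrow - 1])
          uf_union(parent, i, i - nrow - 1);                        // up-left
        if (r < nrow - 1 && c > 0 && fg[i - nrow + 1])
          uf_union(parent, i, i - nrow + 1);                        // down-left
      }
    }
  }

  // second pass: compact root ids into 1..k
  std::vector<int> remap(n, 0);
  int next = 0;
  for (int c = 0; c < ncol; ++c) {
    for (int r = 0; r < nrow; ++r) {
      const int i = c * nrow + r;
      if (!fg[i]) continue;
      int root = uf_find(parent, i);
      if (remap[root] == 0) remap[root] = ++next;
      labels[i] = remap[root];
    }
  }
  return labels;
}
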