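#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Graph-based image segmentation (Felzenszwalb & Huttenlocher, IJCV 2004)
// for a single-channel 2D image. Edges connect 8-neighbours with weight
// |I(a) - I(b)|; regions merge while the connecting edge weight is no larger
// than the internal difference of either region plus scale/|region|.
// Regions smaller than min_size are merged with their most similar neighbour
// in a final pass, as in the reference algorithm.

namespace {

struct DisjointSet {
  std::vector<int> parent, rank_, size_;
  explicit DisjointSet(int n) : parent(n), rank_(n, 0), size_(n, 1) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  int join(int a, int b) {
    if (rank_[a] < rank_[b]) std::swap(a, b);
    parent[b] = a;
    size_[a] += size_[b];
    if (rank_[a] == rank_[b]) ++rank_[a];
    return a;
  }
};

struct Edge { int a, b; double w; };

} // namespace

// [[Rcpp::export(name = ".felz_segment")]]
IntegerMatrix felz_segment(NumericMatrix img, double scale, int min_size) {
  const int nr = img.nrow(), nc = img.ncol();
  const int n = nr * nc;
  auto idx = [nr](int i, int j) { return j * nr + i; };

  std::vector<Edge> edges;
  edges.reserve((size_t)n * 4);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double v = img(i, j);
      if (i + 1 < nr)
        edges.push_back({idx(i, j), idx(i + 1, j), std::abs(v - img(i + 1, j))});
      if (j + 1 < nc)
        edges.push_back({idx(i, j), idx(i, j + 1), std::abs(v - img(i, j + 1))});
      if (i + 1 < nr && j + 1 < nc)
        edges.push_back({idx(i, j), idx(i + 1, j + 1), std::abs(v - img(i + 1, j + 1))});
      if (i > 0 && j + 1 < nc)
        edges.push_back({idx(i, j), idx(i - 1, j + 1), std::abs(v - img(i - 1, j + 1))});
    }
  std::stable_sort(edges.begin(), edges.end(),
                   [](const Edge &x, const Edge &y) { return x.w < y.w; });

  DisjointSet ds(n);
  std::vector<double> threshold(n, scale); // scale / 1
  for (const Edge &e : edges) {
    int a = ds.find(e.a), b = ds.find(e.b);
    if (a == b) continue;
    if (e.w <= threshold[a] && e.w <= threshold[b]) {
      int r = ds.join(a, b);
      threshold[r] = e.w + scale / ds.size_[r];
    }
  }
  // enforce minimum component size
  for (const Edge &e : edges) {
    int a = ds.find(e.a), b = ds.find(e.b);
    if (a != b && (ds.size_[a] < min_size || ds.size_[b] < min_size))
      ds.join(a, b);
  }

  IntegerMatrix out(nr, nc);
  std::vector<int> remap(n, 0);
  int next = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int r = ds.find(idx(i, j));
      if (remap[r] == 0) remap[r] = ++next;
      out(i, j) = remap[r];
    }
  out.attr("n_segments") = next;
  return out;
}
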