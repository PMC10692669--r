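#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Voronoi cells by half-plane intersection, clipped to the ROI frame.
//
// Each cell starts as the frame rectangle and is clipped by the perpendicular
// bisector of its site against every other site (Sutherland-Hodgman). Each
// polygon edge carries the index of the site whose bisector created it (or -1
// for a frame edge), so Voronoi adjacency falls out as the set of surviving
// owner edges of positive length. O(n^2) clips overall, exact for the clipped
// diagram by construction.

struct Pt { double x, y; };

// [[Rcpp::export]]
List voronoi_cells_cpp(NumericVector x, NumericVector y,
                       double xmin, double xmax, double ymin, double ymax) {
  const int n = x.size();
  List polys(n), owners(n);
  std::vector<Pt> poly, next;
  std::vector<int> own, nown;
  poly.reserve(64); next.reserve(64); own.reserve(64); nown.reserve(64);

  for (int i = 0; i < n; ++i) {
    poly = { {xmin, ymin}, {xmax, ymin}, {xmax, ymax}, {xmin, ymax} };
    own = { -1, -1, -1, -1 };
    for (int j = 0; j < n && poly.size() >= 3; ++j) {
      if (j == i) continue;
      // half-plane: points closer to i than to j, a.p <= b
      double ax = x[j] - x[i], ay = y[j] - y[i];
      double b = ax * (x[i] + x[j]) * 0.5 + ay * (y[i] + y[j]) * 0.5;
      next.clear(); nown.clear();
      const int m = poly.size();
      for (int k = 0; k < m; ++k) {
        const Pt &cur = poly[k];
        const Pt &nxt = poly[(k + 1) % m];
        double fc = ax * cur.x + ay * cur.y - b;
        double fn = ax * nxt.x + ay * nxt.y - b;
        bool cin = fc <= 0.0, nin = fn <= 0.0;
        if (cin) {
          next.push_back(cur);
          if (nin) {
            nown.push_back(own[k]);
          } else {
            nown.push_back(own[k]);
            double t = fc / (fc - fn);
            next.push_back({cur.x + t * (nxt.x - cur.x),
                            cur.y + t * (nxt.y - cur.y)});
            nown.push_back(j);  // boundary now runs along the bisector of j
          }
        } else if (nin) {
          double t = fc / (fc - fn);
          next.push_back({cur.x + t * (nxt.x - cur.x),
                          cur.y + t * (nxt.y - cur.y)});
          nown.push_back(own[k]);  // remainder of the original edge k
        }
      }
      poly = next; own = nown;
    }
    const int m = poly.size();
    NumericMatrix P(m, 2);
    IntegerVector O(m);
    for (int k = 0; k < m; ++k) {
      P(k, 0) = poly[k].x; P(k, 1) = poly[k].y;
      O[k] = own[k] >= 0 ? own[k] + 1 : NA_INTEGER;  // 1-based for R
    }
    polys[i] = P; owners[i] = O;
  }
  return List::create(_["polygons"] = polys, _["owners"] = owners);
}

// [[Rcpp::export]]
IntegerMatrix voronoi_adjacency_cpp(List polys, List owners, double min_len) {
  const int n = polys.size();
  std::vector<std::pair<int,int>> edges;
  for (int i = 0; i < n; ++i) {
    NumericMatrix P = polys[i];
    IntegerVector O = owners[i];
    const int m = P.nrow();
    for (int k = 0; k < m; ++k) {
      if (O[k] == NA_INTEGER) continue;
      int j = O[k] - 1;
      if (j <= i) continue;  // record each unordered pair once (from either side)
      int k2 = (k + 1) % m;
      double dx = P(k2, 0) - P(k, 0), dy = P(k2, 1) - P(k, 1);
      if (std::sqrt(dx * dx + dy * dy) > min_len) {
        edges.push_back({i + 1, j + 1});
      }
    }
  }
  // also pick up pairs seen only from the higher-index side
  for (int i = 0; i < n; ++i) {
    NumericMatrix P = polys[i];
    IntegerVector O = owners[i];
    const int m = P.nrow();
    for (int k = 0; k < m; ++k) {
      if (O[k] == NA_INTEGER) continue;
      int j = O[k] - 1;
      if (j >= i) continue;
      int k2 = (k + 1) % m;
      double dx = P(k2, 0) - P(k, 0), dy = P(k2, 1) - P(k, 1);
      if (std::sqrt(dx * dx + dy * dy) > min_len) {
        edges.push_back({j + 1, i + 1});
      }
    }
  }
  std::sort(edges.begin(), edges.end());
  edges.erase(std::unique(edges.begin(), edges.end()), edges.end());
  IntegerMatrix E(edges.size(), 2);
  for (size_t r = 0; r < edges.size(); ++r) {
    E(r, 0) = edges[r].first; E(r, 1) = edges[r].second;
  }
  return E;
}

static int uf_find(std::vector<int> &par, int a) {
  while (par[a] != a) { par[a] = par[par[a]]; a = par[a]; }
  return a;
}

// Number of qualifying microaggregates (connected components of the graph
// restricted to flagged cells that contain >= 1 cell of each flag class) for
// each row of the two permutation matrices. Row 0 of an identity permutation
// gives the observed statistic.
// [[Rcpp::export]]
IntegerVector microagg_counts_cpp(IntegerMatrix edges, LogicalVector flag_t,
                                  LogicalVector flag_i, IntegerMatrix perms_t,
                                  IntegerMatrix perms_i) {
  const int n = flag_t.size();
  const int ne = edges.nrow();
  const int n_iter = perms_t.nrow();
  IntegerVector out(n_iter);
  std::vector<int> par(n);
  std::vector<char> ft(n), fi(n);
  for (int it = 0; it < n_iter; ++it) {
    for (int c = 0; c < n; ++c) {
      ft[c] = flag_t[perms_t(it, c) - 1];
      fi[c] = flag_i[perms_i(it, c) - 1];
      par[c] = c;
    }
    for (int e = 0; e < ne; ++e) {
      int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
      if ((ft[a] || fi[a]) && (ft[b] || fi[b])) {
        int ra = uf_find(par, a), rb = uf_find(par, b);
        if (ra != rb) par[ra] = rb;
      }
    }
    std::vector<char> has_t(n, 0), has_i(n, 0);
    for (int c = 0; c < n; ++c) {
      if (ft[c] || fi[c]) {
        int r = uf_find(par, c);
        if (ft[c]) has_t[r] = 1;
        if (fi[c]) has_i[r] = 1;
      }
    }
    int cnt = 0;
    for (int c = 0; c < n; ++c) if (has_t[c] && has_i[c]) ++cnt;
    out[it] = cnt;
  }
  return out;
}

// Permutation null for phenotype pair interaction counts: labels are shuffled
// over fixed positions; per iteration the edge count between every unordered
// phenotype pair (including same-type) is accumulated.
// edges: 2-column matrix of 1-based cell indices; labels: 1-based phenotype
// codes (1..K). Returns an (n_iter x K*(K+1)/2) matrix of pair counts, pairs
// indexed by (a-1)*K - (a-1)*(a-2)/2 + (b-a) ... flattened as upper triangle
// row-major with a <= b.
// [[Rcpp::export]]
IntegerMatrix permuted_pair_counts_cpp(IntegerMatrix edges, IntegerVector labels,
                                       int K, int n_iter, IntegerMatrix perms) {
  const int ne = edges.nrow();
  const int npair = K * (K + 1) / 2;
  IntegerMatrix out(n_iter, npair);
  std::vector<int> lab(labels.size());
  for (int it = 0; it < n_iter; ++it) {
    for (int c = 0; c < (int)lab.size(); ++c) lab[c] = labels[perms(it, c) - 1];
    for (int e = 0; e < ne; ++e) {
      int a = lab[edges(e, 0) - 1], b = lab[edges(e, 1) - 1];
      if (a > b) std::swap(a, b);
      int idx = (a - 1) * K - (a - 1) * (a - 2) / 2 + (b - a);
      out(it, idx)++;
    }
  }
  return out;
}
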