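// Vietoris-Rips persistent homology over Z/2.
//
// Pairs are computed by the persistent-cohomology reduction (the
// anti-transpose of the boundary reduction): within each dimension d,
// columns are the d-simplices processed in decreasing filtration order,
// entries are their cofacets, and the pivot is the cofacet earliest in the
// filtration.  Clearing skips columns already identified as pivots in the
// previous dimension (dimension 0 is handled by a union-find pass over the
// sorted edges).  Simplices are ordered by (diameter, packed vertex key);
// faces always precede cofaces since a face's diameter is no larger and its
// dimension is smaller.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <queue>
#include <vector>

using namespace Rcpp;

namespace {

typedef std::uint64_t key_t_;

struct Simplex {
  double diam;
  key_t_ key;  // vertices packed 16 bits each, smallest vertex in high bits
};

inline bool simplex_less(const Simplex& a, const Simplex& b) {
  if (a.diam != b.diam) return a.diam < b.diam;
  return a.key < b.key;
}

inline key_t_ pack2(int i, int j) {
  return (static_cast<key_t_>(i) << 16) | static_cast<key_t_>(j);
}

inline void unpack(key_t_ key, int d, int* verts) {
  // d+1 vertices, most significant block first
  for (int a = d; a >= 0; --a) {
    verts[a] = static_cast<int>(key & 0xFFFF);
    key >>= 16;
  }
}

inline key_t_ insert_vertex(key_t_ key, int d, int w) {
  // insert w into the sorted packed vertex list (d+1 existing vertices)
  int verts[5];
  unpack(key, d, verts);
  key_t_ out = 0;
  int a = 0;
  bool placed = false;
  for (int b = 0; b <= d + 1; ++b) {
    int v;
    if (!placed && (a > d || w < verts[a])) {
      v = w;
      placed = true;
    } else {
      v = verts[a++];
    }
    out = (out << 16) | static_cast<key_t_>(v);
  }
  return out;
}

struct DistView {
  const double* d;
  int n;
  inline double operator()(int i, int j) const { return d[i + static_cast<std::size_t>(j) * n]; }
};

// pop the pivot (minimum rank) of a Z/2 column heap, cancelling duplicates
inline int pop_pivot(std::priority_queue<int, std::vector<int>, std::greater<int> >& q) {
  while (!q.empty()) {
    int p = q.top();
    q.pop();
    if (q.empty() || q.top() != p) return p;
    q.pop();  // duplicate: cancels over Z/2
  }
  return -1;
}

struct UnionFind {
  std::vector<int> parent;
  explicit UnionFind(int n) : parent(n) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  }
};

// rank lookup for a simplex dimension: keys sorted by key value
struct RankIndex {
  std::vector<key_t_> keys;   // sorted
  std::vector<int> rank;      // rank[i] = filtration rank of keys[i]
  void build(const std::vector<Simplex>& simps) {
    std::vector<std::pair<key_t_, int> > tmp(simps.size());
    for (std::size_t i = 0; i < simps.size(); ++i)
      tmp[i] = std::make_pair(simps[i].key, static_cast<int>(i));
    std::sort(tmp.begin(), tmp.end());
    keys.resize(tmp.size());
    rank.resize(tmp.size());
    for (std::size_t i = 0; i < tmp.size(); ++i) {
      keys[i] = tmp[i].first;
      rank[i] = tmp[i].second;
    }
  }
  int lookup(key_t_ k) const {
    std::vector<key_t_>::const_iterator it =
        std::lower_bound(keys.begin(), keys.end(), k);
    if (it == keys.end() || *it != k) return -1;
    return rank[it - keys.begin()];
  }
};

}  // namespace

// [[Rcpp::export(name = ".rips_persistence", rng = false)]]
List rips_persistence(NumericMatrix dist, double threshold, int max_dim) {
  const int n = dist.nrow();
  if (n > 60000) stop("too many points");
  if (max_dim > 3) stop("max_dim above 3 is not supported");
  DistView D;
  D.d = REAL(dist);
  D.n = n;

  // ---- enumerate simplices per dimension ------------------------------
  std::vector<std::vector<Simplex> > simp(max_dim + 2);
  // edges
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dij = D(i, j);
      if (dij <= threshold) {
        Simplex s;
        s.diam = dij;
        s.key = pack2(i, j);
        simp[1].push_back(s);
      }
    }
  }
  // triangles and tetrahedra by extension with a larger vertex
  for (int d = 2; d <= max_dim + 1; ++d) {
    const std::vector<Simplex>& prev = simp[d - 1];
    std::vector<Simplex>& cur = simp[d];
    int verts[5];
    for (std::size_t s = 0; s < prev.size(); ++s) {
      unpack(prev[s].key, d - 1, verts);
      int last = verts[d - 1];
      for (int w = last + 1; w < n; ++w) {
        double diam = prev[s].diam;
        bool ok = true;
        for (int a = 0; a < d; ++a) {
          double dv = D(verts[a], w);
          if (dv > threshold) {
            ok = false;
            break;
          }
          if (dv > diam) diam = dv;
        }
        if (!ok) continue;
        Simplex t;
        t.diam = diam;
        t.key = (prev[s].key << 16) | static_cast<key_t_>(w);
        cur.push_back(t);
      }
    }
  }
  for (int d = 1; d <= max_dim + 1; ++d) {
    if (simp[d].size() > 60000000u) {
      stop("Vietoris-Rips skeleton too large (dimension %d has %d simplices); "
           "reduce the landmark count or threshold",
           d, static_cast<int>(simp[d].size()));
    }
    std::sort(simp[d].begin(), simp[d].end(), simplex_less);
  }

  std::vector<std::vector<double> > births(max_dim + 1), deaths(max_dim + 1);

  // ---- dimension 0: union-find over sorted edges ----------------------
  UnionFind uf(n);
  std::vector<char> cleared(simp[1].size(), 0);  // death edges
  for (std::size_t e = 0; e < simp[1].size(); ++e) {
    int verts[2];
    unpack(simp[1][e].key, 1, verts);
    int ra = uf.find(verts[0]), rb = uf.find(verts[1]);
    if (ra != rb) {
      uf.parent[ra] = rb;
      births[0].push_back(0.0);
      deaths[0].push_back(simp[1][e].diam);
      cleared[e] = 1;
    }
  }
  {
    int comps = 0;
    for (int i = 0; i < n; ++i)
      if (uf.find(i) == i) ++comps;
    for (int c = 0; c < comps; ++c) {
      births[0].push_back(0.0);
      deaths[0].push_back(R_PosInf);
    }
  }

  // ---- dimensions 1..max_dim: cohomology reduction with clearing ------
  typedef std::priority_queue<int, std::vector<int>, std::greater<int> > Heap;
  int verts[5];
  for (int d = 1; d <= max_dim; ++d) {
    const std::vector<Simplex>& cols = simp[d];
    const std::vector<Simplex>& rows = simp[d + 1];
    RankIndex ridx;
    ridx.build(rows);
    std::vector<char> row_cleared(rows.size(), 0);
    // reduced columns stored without their pivot entry
    std::vector<std::vector<int> > store;
    std::vector<int> pivot_owner(rows.size(), -1);

    for (int c = static_cast<int>(cols.size()) - 1; c >= 0; --c) {
      if (cleared[c]) continue;
      unpack(cols[c].key, d, verts);
      Heap heap;
      // cofacets: add any vertex adjacent (within threshold) to all of ours
      for (int w = 0; w < n; ++w) {
        bool member = false;
        for (int a = 0; a <= d; ++a)
          if (verts[a] == w) {
            member = true;
            break;
          }
        if (member) continue;
        bool ok = true;
        for (int a = 0; a <= d; ++a) {
          if (D(verts[a], w) > threshold) {
            ok = false;
            break;
          }
        }
        if (!ok) continue;
        int r = ridx.lookup(insert_vertex(cols[c].key, d, w));
        if (r >= 0) heap.push(r);
      }
      int pivot;
      for (;;) {
        pivot = pop_pivot(heap);
        if (pivot < 0) break;
        int owner = pivot_owner[pivot];
        if (owner < 0) break;
        const std::vector<int>& other = store[owner];
        for (std::size_t k = 0; k < other.size(); ++k) heap.push(other[k]);
        // stored column excludes its pivot, which cancels the popped one
      }
      if (pivot < 0) {
        births[d].push_back(cols[c].diam);
        deaths[d].push_back(R_PosInf);
      } else {
        if (rows[pivot].diam > cols[c].diam) {
          births[d].push_back(cols[c].diam);
          deaths[d].push_back(rows[pivot].diam);
        }
        row_cleared[pivot] = 1;
        std::vector<int> rest;
        int e;
        while ((e = pop_pivot(heap)) >= 0) rest.push_back(e);
        pivot_owner[pivot] = static_cast<int>(store.size());
        store.push_back(rest);
      }
      if (c % 4096 == 0) Rcpp::checkUserInterrupt();
    }
    cleared.swap(row_cleared);
  }

  List out(max_dim + 1);
  for (int d = 0; d <= max_dim; ++d) {
    NumericMatrix m(static_cast<int>(births[d].size()), 2);
    for (std::size_t i = 0; i < births[d].size(); ++i) {
      m(static_cast<int>(i), 0) = births[d][i];
      m(static_cast<int>(i), 1) = deaths[d][i];
    }
    colnames(m) = CharacterVector::create("birth", "death");
    out[d] = m;
  }
  return out;
}
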