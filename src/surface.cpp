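// Frontier dynamic-programming cores for the solution-surface algorithms.
//
// Cost points (r = switches, m = mismatches) are exact integers; every
// frontier is the strictly convex lower-left hull of its candidate set, so
// all arithmetic below is integer and the results are deterministic.
// Candidate preference on exact (r, m) ties is encoded by listing order
// (fewer switches first, then lower template / pair index), matching the
// R-level reference implementation.

#include <Rcpp.h>

#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

struct Cand {
  int r, m;
  int src;    // backpointer node id of the parent vertex
  int tag;    // candidate class (haploid: 0 stay / 1 switch; diploid: case)
  int keep;   // diploid single-switch: the continuing template
  int ord;    // listing order, for stable tie preference
};

struct Chain {
  std::vector<int> r, m, id;
  void clear() { r.clear(); m.clear(); id.clear(); }
  size_t size() const { return r.size(); }
};

// backpointer store
struct Store {
  std::vector<int> parent, label1, label2, kind, keepn;
  int add(int p, int l1, int l2, int k, int kp) {
    parent.push_back(p);
    label1.push_back(l1);
    label2.push_back(l2);
    kind.push_back(k);
    keepn.push_back(kp);
    return static_cast<int>(parent.size()) - 1;  // 0-based ids; -1 = root
  }
};

// strictly convex lower-left hull of the candidates; ties on (r, m) go to
// the lowest listing order.  Candidates need not be sorted.
void lll_hull(std::vector<Cand>& c, std::vector<Cand>& out) {
  std::sort(c.begin(), c.end(), [](const Cand& a, const Cand& b) {
    if (a.r != b.r) return a.r < b.r;
    if (a.m != b.m) return a.m < b.m;
    return a.ord < b.ord;
  });
  // pointwise-min reduction over duplicate r
  size_t w = 0;
  for (size_t i = 0; i < c.size(); ++i) {
    if (i == 0 || c[i].r != c[w - 1].r) c[w++] = c[i];
  }
  c.resize(w);
  // truncate at the first r attaining the minimal m
  int mmin = c[0].m;
  size_t cut = 0;
  for (size_t i = 1; i < c.size(); ++i) {
    if (c[i].m < mmin) { mmin = c[i].m; cut = i; }
  }
  c.resize(cut + 1);
  // monotone chain, strict convexity (collinear interior points dropped)
  out.clear();
  for (const Cand& p : c) {
    while (out.size() >= 2) {
      const Cand& a = out[out.size() - 2];
      const Cand& b = out[out.size() - 1];
      long long lhs = static_cast<long long>(b.m - a.m) * (p.r - b.r);
      long long rhs = static_cast<long long>(p.m - b.m) * (b.r - a.r);
      if (lhs >= rhs) out.pop_back(); else break;
    }
    out.push_back(p);
  }
}

void merge_into(const std::vector<Chain>& chains, std::vector<Cand>& buf,
                std::vector<Cand>& hull, Chain& G) {
  buf.clear();
  int ord = 0;
  for (const Chain& ch : chains) {
    for (size_t i = 0; i < ch.size(); ++i) {
      buf.push_back({ch.r[i], ch.m[i], ch.id[i], 0, 0, ord++});
    }
  }
  lll_hull(buf, hull);
  G.clear();
  for (const Cand& p : hull) {
    G.r.push_back(p.r);
    G.m.push_back(p.m);
    G.id.push_back(p.src);
  }
}

}  // namespace

// [[Rcpp::export(name = ".ls_haploid_core")]]
List ls_haploid_core(const IntegerMatrix& D) {
  const int L = D.nrow(), N = D.ncol();
  Store st;
  std::vector<Chain> F(N);
  Chain G;
  std::vector<Cand> buf, hull;

  for (int n = 0; n < N; ++n) {
    int id = st.add(-1, n, 0, 0, 0);
    F[n].r.push_back(0);
    F[n].m.push_back(D(0, n));
    F[n].id.push_back(id);
  }
  merge_into(F, buf, hull, G);

  for (int l = 1; l < L; ++l) {
    Chain Gprev = G;  // frontier at the previous site
    for (int n = 0; n < N; ++n) {
      const int d = D(l, n);
      buf.clear();
      int ord = 0;
      Chain& fn = F[n];
      for (size_t i = 0; i < fn.size(); ++i) {
        buf.push_back({fn.r[i], fn.m[i] + d, fn.id[i], 0, 0, ord++});
      }
      for (size_t i = 0; i < Gprev.size(); ++i) {
        buf.push_back({Gprev.r[i] + 1, Gprev.m[i] + d, Gprev.id[i], 1, 0, ord++});
      }
      lll_hull(buf, hull);
      fn.clear();
      for (const Cand& p : hull) {
        int id = st.add(p.src, n, 0, p.tag, 0);
        fn.r.push_back(p.r);
        fn.m.push_back(p.m);
        fn.id.push_back(id);
      }
    }
    merge_into(F, buf, hull, G);
  }

  const int M = static_cast<int>(G.size());
  IntegerVector r(M), m(M);
  IntegerMatrix paths(M, L);
  for (int i = 0; i < M; ++i) {
    r[i] = G.r[i];
    m[i] = G.m[i];
    int id = G.id[i];
    for (int l = L - 1; l >= 0; --l) {
      if (id < 0) stop("corrupted provenance: backpointer chain too short");
      paths(i, l) = st.label1[id] + 1;  // back to 1-based templates
      id = st.parent[id];
    }
    if (id != -1) stop("corrupted provenance: backpointer chain too long");
  }
  return List::create(_["r"] = r, _["m"] = m, _["paths"] = paths);
}

// per-site unordered-pair mismatch |{g1,g2} symdiff {a1,a2}|, set semantics
static inline int pair_mismatch(int g1, int g2, int a1, int a2) {
  const int sizeA = 1 + (g1 != g2);
  const int sizeB = 1 + (a1 != a2);
  const int inter = ((a1 == g1 || a1 == g2) ? 1 : 0) +
                    ((a2 != a1 && (a2 == g1 || a2 == g2)) ? 1 : 0);
  return sizeA + sizeB - 2 * inter;
}

// [[Rcpp::export(name = ".ls_diploid_core")]]
List ls_diploid_core(const IntegerMatrix& G_alleles, const IntegerMatrix& H) {
  const int L = H.nrow(), N = H.ncol();
  const int npair = N * (N + 1) / 2;
  std::vector<int> n1_of(npair), n2_of(npair);
  {
    int k = 0;
    for (int a = 0; a < N; ++a)
      for (int b = a; b < N; ++b) { n1_of[k] = a; n2_of[k] = b; ++k; }
  }

  Store st;
  std::vector<Chain> FP(npair), P(N);
  Chain G;
  std::vector<Cand> buf, hull;
  std::vector<int> d(npair);

  auto site_mismatches = [&](int l) {
    for (int p = 0; p < npair; ++p) {
      d[p] = pair_mismatch(G_alleles(l, 0), G_alleles(l, 1),
                           H(l, n1_of[p]), H(l, n2_of[p]));
    }
  };

  auto rebuild_partials = [&]() {
    std::vector<Chain> members;
    for (int n = 0; n < N; ++n) {
      members.clear();
      for (int p = 0; p < npair; ++p) {
        if (n1_of[p] == n || n2_of[p] == n) members.push_back(FP[p]);
      }
      merge_into(members, buf, hull, P[n]);
    }
  };

  site_mismatches(0);
  for (int p = 0; p < npair; ++p) {
    int id = st.add(-1, n1_of[p], n2_of[p], 1, 0);
    FP[p].r.push_back(0);
    FP[p].m.push_back(d[p]);
    FP[p].id.push_back(id);
  }
  rebuild_partials();
  merge_into(FP, buf, hull, G);

  for (int l = 1; l < L; ++l) {
    site_mismatches(l);
    Chain Gprev = G;
    std::vector<Chain> Pprev = P;
    for (int p = 0; p < npair; ++p) {
      const int n1 = n1_of[p], n2 = n2_of[p], dp = d[p];
      buf.clear();
      int ord = 0;
      Chain& fp = FP[p];
      for (size_t i = 0; i < fp.size(); ++i)
        buf.push_back({fp.r[i], fp.m[i] + dp, fp.id[i], 1, 0, ord++});
      const Chain& P1 = Pprev[n1];
      for (size_t i = 0; i < P1.size(); ++i)
        buf.push_back({P1.r[i] + 1, P1.m[i] + dp, P1.id[i], 2, n1, ord++});
      if (n2 != n1) {
        const Chain& P2 = Pprev[n2];
        for (size_t i = 0; i < P2.size(); ++i)
          buf.push_back({P2.r[i] + 1, P2.m[i] + dp, P2.id[i], 2, n2, ord++});
      }
      for (size_t i = 0; i < Gprev.size(); ++i)
        buf.push_back({Gprev.r[i] + 2, Gprev.m[i] + dp, Gprev.id[i], 4, 0, ord++});
      lll_hull(buf, hull);
      fp.clear();
      for (const Cand& q : hull) {
        int id = st.add(q.src, n1, n2, q.tag, q.keep);
        fp.r.push_back(q.r);
        fp.m.push_back(q.m);
        fp.id.push_back(id);
      }
    }
    rebuild_partials();
    merge_into(FP, buf, hull, G);
  }

  const int M = static_cast<int>(G.size());
  IntegerVector r(M), m(M);
  IntegerMatrix path1(M, L), path2(M, L);
  std::vector<int> a(L), b(L), kind(L), keepn(L);
  for (int i = 0; i < M; ++i) {
    r[i] = G.r[i];
    m[i] = G.m[i];
    int id = G.id[i];
    for (int l = L - 1; l >= 0; --l) {
      if (id < 0) stop("corrupted provenance: backpointer chain too short");
      a[l] = st.label1[id];
      b[l] = st.label2[id];
      kind[l] = st.kind[id];
      keepn[l] = st.keepn[id];
      id = st.parent[id];
    }
    if (id != -1) stop("corrupted provenance: backpointer chain too long");
    // forward pass: orient the unordered pairs so the realized switch
    // counts sum exactly to the vertex's r
    int p1 = a[0], p2 = b[0];
    path1(i, 0) = p1 + 1;
    path2(i, 0) = p2 + 1;
    for (int l = 1; l < L; ++l) {
      if (kind[l] == 1) {
        // no switch: keep the previous orientation
      } else if (kind[l] == 2) {
        const int tk = keepn[l];
        const int to = (a[l] == tk) ? b[l] : a[l];
        if (p1 == tk) p2 = to;
        else { p2 = tk; p1 = to; }
      } else {
        if (a[l] != p1 && b[l] != p2) { p1 = a[l]; p2 = b[l]; }
        else { p1 = b[l]; p2 = a[l]; }
      }
      path1(i, l) = p1 + 1;
      path2(i, l) = p2 + 1;
    }
  }
  return List::create(_["r"] = r, _["m"] = m,
                      _["path1"] = path1, _["path2"] = path2);
}
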