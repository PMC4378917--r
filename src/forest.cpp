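// Classification random forest on mixed-type features.
//
// Features arrive as a numeric matrix; categorical columns are coded
// 1..L with L given in `ncat` (0 marks a continuous column).  Trees are
// unpruned CART: at each node `mtry` candidate variables are drawn
// without replacement and the best split by Gini impurity decrease is
// taken.  Any valid split (both children non-empty) is acceptable even
// at zero gain, so separable interactions (e.g. XOR) are still resolved;
// recursion terminates because children are strictly smaller.  Ties are
// broken deterministically: lowest variable index, then lowest
// threshold / lowest level-subset code.
//
// All randomness comes from a self-contained xoroshiro128+ stream.  The
// per-tree seed is a fixed function of (forest seed, tree index), so
// growing more trees never reshuffles earlier ones.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoro {
  uint64_t s[2];
  explicit Xoro(uint64_t seed) {
    uint64_t x = seed;
    s[0] = splitmix64(x);
    s[1] = splitmix64(x);
    if (!(s[0] | s[1])) s[0] = 0x1ULL;
  }
  uint64_t next() {
    uint64_t a = s[0], b = s[1], r = a + b;
    b ^= a;
    s[0] = ((a << 55) | (a >> 9)) ^ b ^ (b << 14);
    s[1] = (b << 36) | (b >> 28);
    return r;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int unif_int(int n) {  // 0..n-1
    int r = (int)(unif() * n);
    return r >= n ? n - 1 : r;
  }
  void shuffle(std::vector<int> &v) {
    for (int i = (int)v.size() - 1; i > 0; --i) {
      int j = unif_int(i + 1);
      std::swap(v[i], v[j]);
    }
  }
};

static inline uint64_t tree_seed(uint64_t base, int t) {
  uint64_t x = base ^ (0x9E3779B97F4A7C15ULL * (uint64_t)(t + 1));
  return splitmix64(x);
}

struct Tree {
  std::vector<int> var, left, right, cls;
  std::vector<double> thr;
  std::vector<int> mask;  // go-left level bitmask (level l -> bit l-1)
  int add_node() {
    var.push_back(-1); left.push_back(-1); right.push_back(-1);
    cls.push_back(-1); thr.push_back(NA_REAL); mask.push_back(0);
    return (int)var.size() - 1;
  }
};

static inline double gini_from_counts(const std::vector<double> &cnt, double m) {
  if (m <= 0) return 0.0;
  double s = 0.0;
  for (double c : cnt) s += c * c;
  return 1.0 - s / (m * m);
}

struct Grower {
  const NumericMatrix &X;
  const IntegerVector &ncat;
  const std::vector<int> &y;
  int nclass, mtry, min_node, p;
  Xoro &rng;
  Tree tree;

  Grower(const NumericMatrix &X_, const IntegerVector &ncat_,
         const std::vector<int> &y_, int nclass_, int mtry_, int min_node_,
         Xoro &rng_)
      : X(X_), ncat(ncat_), y(y_), nclass(nclass_), mtry(mtry_),
        min_node(min_node_), p(X_.ncol()), rng(rng_) {}

  int majority(const std::vector<int> &rows) {
    std::vector<int> cnt(nclass, 0);
    for (int r : rows) cnt[y[r]]++;
    int best = 0;
    for (int c = 1; c < nclass; ++c) if (cnt[c] > cnt[best]) best = c;
    return best;
  }

  // Best split on variable v among rows.  Returns true if a valid split
  // exists with gain >= current best (strictly better by >1e-12).
  bool best_split_var(const std::vector<int> &rows, int v, double parent_gini,
                      double &best_gain, double &best_thr, int &best_mask,
                      bool &best_is_cat) {
    int m = (int)rows.size();
    bool improved = false;
    if (ncat[v] == 0) {
      std::vector<std::pair<double, int>> vals(m);
      for (int i = 0; i < m; ++i) vals[i] = {X(rows[i], v), y[rows[i]]};
      std::sort(vals.begin(), vals.end());
      std::vector<double> lc(nclass, 0.0), rc(nclass, 0.0);
      for (int i = 0; i < m; ++i) rc[vals[i].second] += 1.0;
      for (int i = 0; i < m - 1; ++i) {
        lc[vals[i].second] += 1.0;
        rc[vals[i].second] -= 1.0;
        if (vals[i + 1].first > vals[i].first) {
          double nl = i + 1.0, nr = m - nl;
          double gain = parent_gini -
                        (nl / m) * gini_from_counts(lc, nl) -
                        (nr / m) * gini_from_counts(rc, nr);
          if (gain > best_gain + 1e-12) {
            best_gain = gain;
            best_thr = vals[i].first + (vals[i + 1].first - vals[i].first) / 2.0;
            best_is_cat = false;
            improved = true;
          }
        }
      }
    } else {
      int L = ncat[v];
      if (L > 30) stop("categorical variable with more than 30 levels");
      std::vector<std::vector<double>> lev_cnt(L, std::vector<double>(L ? nclass : 0, 0.0));
      std::vector<double> lev_tot(L, 0.0);
      for (int i = 0; i < m; ++i) {
        int lev = (int)X(rows[i], v) - 1;
        lev_cnt[lev][y[rows[i]]] += 1.0;
        lev_tot[lev] += 1.0;
      }
      std::vector<int> present;
      for (int l = 0; l < L; ++l) if (lev_tot[l] > 0) present.push_back(l);
      int np = (int)present.size();
      if (np < 2) return false;
      // lowest present level is pinned left to avoid mirror duplicates;
      // subsets enumerated in ascending code order for deterministic ties
      int nsub = 1 << (np - 1);
      for (int sub = 0; sub < nsub - 1; ++sub) {
        std::vector<double> lc(nclass, 0.0);
        double nl = 0.0;
        int mask = 1 << present[0];
        lc = lev_cnt[present[0]];
        nl = lev_tot[present[0]];
        for (int j = 0; j < np - 1; ++j) {
          if (sub & (1 << j)) {
            int l = present[j + 1];
            mask |= (1 << l);
            for (int c = 0; c < nclass; ++c) lc[c] += lev_cnt[l][c];
            nl += lev_tot[l];
          }
        }
        double nr = m - nl;
        if (nl <= 0 || nr <= 0) continue;
        std::vector<double> rc(nclass, 0.0);
        for (int c = 0; c < nclass; ++c) {
          double tot = 0.0;
          for (int l : present) tot += lev_cnt[l][c];
          rc[c] = tot - lc[c];
        }
        double gain = parent_gini -
                      (nl / m) * gini_from_counts(lc, nl) -
                      (nr / m) * gini_from_counts(rc, nr);
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_mask = mask;
          best_is_cat = true;
          improved = true;
        }
      }
    }
    return improved;
  }

  int grow(std::vector<int> &rows) {
    int id = tree.add_node();
    int m = (int)rows.size();
    std::vector<double> cnt(nclass, 0.0);
    for (int r : rows) cnt[y[r]] += 1.0;
    int npos = 0;
    for (double c : cnt) if (c > 0) npos++;
    if (npos <= 1 || m < 2 || m < min_node) {
      tree.cls[id] = majority(rows);
      return id;
    }
    // draw mtry candidate variables without replacement, evaluate in
    // ascending index order so ties resolve to the lowest variable
    std::vector<int> cand(p);
    for (int j = 0; j < p; ++j) cand[j] = j;
    rng.shuffle(cand);
    cand.resize(mtry);
    std::sort(cand.begin(), cand.end());

    double parent_gini = gini_from_counts(cnt, (double)m);
    double best_gain = -1e300, best_thr = NA_REAL;
    int best_var = -1, best_mask = 0;
    bool best_is_cat = false;
    for (int v : cand) {
      if (best_split_var(rows, v, parent_gini, best_gain, best_thr, best_mask,
                         best_is_cat))
        best_var = v;
    }
    if (best_var < 0) {  // no valid split among candidates
      tree.cls[id] = majority(rows);
      return id;
    }
    std::vector<int> lrows, rrows;
    for (int r : rows) {
      bool go_left;
      if (best_is_cat) {
        int lev = (int)X(r, best_var) - 1;
        go_left = (best_mask >> lev) & 1;
      } else {
        go_left = X(r, best_var) <= best_thr;
      }
      (go_left ? lrows : rrows).push_back(r);
    }
    tree.var[id] = best_var;
    if (best_is_cat) tree.mask[id] = best_mask; else tree.thr[id] = best_thr;
    tree.left[id] = grow(lrows);
    tree.right[id] = grow(rrows);
    return id;
  }
};

// Traverse a serialized tree for row `i` of X; `perm_var`/`perm_val`
// optionally override one variable's value (permutation importance).
static int traverse(const IntegerVector &var, const NumericVector &thr,
                    const IntegerVector &mask, const IntegerVector &left,
                    const IntegerVector &right, const IntegerVector &ncat,
                    const NumericMatrix &X, int i, int perm_var = -1,
                    double perm_val = 0.0) {
  int node = 0;
  while (var[node] >= 0) {
    int v = var[node];
    double x = (v == perm_var) ? perm_val : X(i, v);
    bool go_left;
    if (ncat[v] > 0) {
      int lev = (int)x - 1;
      go_left = (mask[node] >> lev) & 1;
    } else {
      go_left = x <= thr[node];
    }
    node = go_left ? left[node] : right[node];
  }
  return node;
}

// [[Rcpp::export]]
List rf_grow_forest(NumericMatrix X, IntegerVector ncat, IntegerVector y,
                    int nclass, int ntree, int mtry, int min_node,
                    double seed) {
  int n = X.nrow();
  std::vector<int> yy(y.begin(), y.end());
  uint64_t base = (uint64_t)seed;
  List trees(ntree);
  IntegerMatrix inbag(n, ntree);
  for (int t = 0; t < ntree; ++t) {
    Xoro rng(tree_seed(base, t));
    std::vector<int> count(n, 0);
    for (int d = 0; d < n; ++d) count[rng.unif_int(n)]++;
    std::vector<int> rows;
    rows.reserve(n);
    for (int i = 0; i < n; ++i) {
      inbag(i, t) = count[i];
      for (int c = 0; c < count[i]; ++c) rows.push_back(i);
    }
    Grower g(X, ncat, yy, nclass, mtry, min_node, rng);
    g.grow(rows);
    trees[t] = List::create(
        Named("var") = IntegerVector(g.tree.var.begin(), g.tree.var.end()),
        Named("thr") = NumericVector(g.tree.thr.begin(), g.tree.thr.end()),
        Named("mask") = IntegerVector(g.tree.mask.begin(), g.tree.mask.end()),
        Named("left") = IntegerVector(g.tree.left.begin(), g.tree.left.end()),
        Named("right") = IntegerVector(g.tree.right.begin(), g.tree.right.end()),
        Named("cls") = IntegerVector(g.tree.cls.begin(), g.tree.cls.end()));
  }
  return List::create(Named("trees") = trees, Named("inbag") = inbag);
}

// Grow one tree on the rows as given (no bootstrap): the tree-level
// contract used by unit tests and by single-tree inspection.
// [[Rcpp::export]]
List rf_grow_single_tree(NumericMatrix X, IntegerVector ncat, IntegerVector y,
                         int nclass, int mtry, int min_node, double seed) {
  std::vector<int> yy(y.begin(), y.end());
  Xoro rng(tree_seed((uint64_t)seed, 0));
  std::vector<int> rows(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) rows[i] = i;
  Grower g(X, ncat, yy, nclass, mtry, min_node, rng);
  g.grow(rows);
  return List::create(
      Named("var") = IntegerVector(g.tree.var.begin(), g.tree.var.end()),
      Named("thr") = NumericVector(g.tree.thr.begin(), g.tree.thr.end()),
      Named("mask") = IntegerVector(g.tree.mask.begin(), g.tree.mask.end()),
      Named("left") = IntegerVector(g.tree.left.begin(), g.tree.left.end()),
      Named("right") = IntegerVector(g.tree.right.begin(), g.tree.right.end()),
      Named("cls") = IntegerVector(g.tree.cls.begin(), g.tree.cls.end()));
}

// [[Rcpp::export]]
IntegerMatrix rf_leaf_ids(List trees, NumericMatrix X, IntegerVector ncat) {
  int n = X.nrow(), ntree = trees.size();
  IntegerMatrix out(n, ntree);
  for (int t = 0; t < ntree; ++t) {
    List tr = trees[t];
    IntegerVector var = tr["var"], mask = tr["mask"], left = tr["left"],
                  right = tr["right"];
    NumericVector thr = tr["thr"];
    for (int i = 0; i < n; ++i)
      out(i, t) = traverse(var, thr, mask, left, right, ncat, X, i);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix rf_proximity_from_leaves(IntegerMatrix leaves,
                                       Nullable<IntegerMatrix> inbag_,
                                       bool oob_only) {
  int n = leaves.nrow(), ntree = leaves.ncol();
  NumericMatrix P(n, n);
  if (!oob_only) {
    for (int t = 0; t < ntree; ++t) {
      std::vector<int> ord(n);
      for (int i = 0; i < n; ++i) ord[i] = i;
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        return leaves(a, t) < leaves(b, t);
      });
      int i = 0;
      while (i < n) {
        int j = i;
        while (j < n && leaves(ord[j], t) == leaves(ord[i], t)) ++j;
        for (int a = i; a < j; ++a)
          for (int b = i; b < j; ++b) P(ord[a], ord[b]) += 1.0;
        i = j;
      }
    }
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) P(i, j) /= (double)ntree;
  } else {
    if (inbag_.isNull()) stop("inbag required for OOB proximity");
    IntegerMatrix inbag(inbag_);
    NumericMatrix denom(n, n);
    for (int t = 0; t < ntree; ++t) {
      std::vector<int> oob;
      for (int i = 0; i < n; ++i) if (inbag(i, t) == 0) oob.push_back(i);
      for (size_t a = 0; a < oob.size(); ++a)
        for (size_t b = 0; b < oob.size(); ++b) {
          denom(oob[a], oob[b]) += 1.0;
          if (leaves(oob[a], t) == leaves(oob[b], t))
            P(oob[a], oob[b]) += 1.0;
        }
    }
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        P(i, j) = denom(i, j) > 0 ? P(i, j) / denom(i, j) : 0.0;
  }
  for (int i = 0; i < n; ++i) P(i, i) = 1.0;
  return P;
}

// [[Rcpp::export]]
IntegerMatrix rf_oob_votes(List trees, IntegerMatrix inbag, NumericMatrix X,
                           IntegerVector ncat, int nclass) {
  int n = X.nrow(), ntree = trees.size();
  IntegerMatrix votes(n, nclass);
  for (int t = 0; t < ntree; ++t) {
    List tr = trees[t];
    IntegerVector var = tr["var"], mask = tr["mask"], left = tr["left"],
                  right = tr["right"], cls = tr["cls"];
    NumericVector thr = tr["thr"];
    for (int i = 0; i < n; ++i) {
      if (inbag(i, t) != 0) continue;
      int leaf = traverse(var, thr, mask, left, right, ncat, X, i);
      votes(i, cls[leaf]) += 1;
    }
  }
  return votes;
}

// Per-tree, per-variable decrease in OOB accuracy after permuting that
// variable's values among the tree's OOB rows.  Returns ntree x p; NA
// rows for trees with no OOB observations.
// [[Rcpp::export]]
NumericMatrix rf_perm_importance_cpp(List trees, IntegerMatrix inbag,
                                     NumericMatrix X, IntegerVector ncat,
                                     IntegerVector y, double seed) {
  int n = X.nrow(), p = X.ncol(), ntree = trees.size();
  uint64_t base = (uint64_t)seed ^ 0xA5A5A5A5DEADBEEFULL;
  NumericMatrix out(ntree, p);
  for (int t = 0; t < ntree; ++t) {
    List tr = trees[t];
    IntegerVector var = tr["var"], mask = tr["mask"], left = tr["left"],
                  right = tr["right"], cls = tr["cls"];
    NumericVector thr = tr["thr"];
    std::vector<int> oob;
    for (int i = 0; i < n; ++i) if (inbag(i, t) == 0) oob.push_back(i);
    int no = (int)oob.size();
    if (no == 0) {
      for (int v = 0; v < p; ++v) out(t, v) = NA_REAL;
      continue;
    }
    int correct0 = 0;
    for (int i : oob) {
      int leaf = traverse(var, thr, mask, left, right, ncat, X, i);
      if (cls[leaf] == y[i]) correct0++;
    }
    for (int v = 0; v < p; ++v) {
      // per-(tree, variable) substream: deterministic regardless of
      // evaluation order
      uint64_t s = tree_seed(base, t) ^ (0xC2B2AE3D27D4EB4FULL * (uint64_t)(v + 1));
      Xoro rng(splitmix64(s));
      std::vector<int> perm(no);
      for (int i = 0; i < no; ++i) perm[i] = i;
      rng.shuffle(perm);
      int correct = 0;
      for (int i = 0; i < no; ++i) {
        double pv = X(oob[perm[i]], v);
        int leaf = traverse(var, thr, mask, left, right, ncat, X, oob[i], v, pv);
        if (cls[leaf] == y[oob[i]]) correct++;
      }
      out(t, v) = (double)(correct0 - correct) / (double)no;
    }
  }
  return out;
}
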