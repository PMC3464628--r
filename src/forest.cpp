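#include <Rcpp.h>
using namespace Rcpp;

// Random-forest core for binary (0/1) predictors. A tree is a set of
// parallel arrays: var (split item, -1 for leaf), kid0/kid1 (child node
// for item value 0/1), leaf_class (majority class, ties to lowest class
// index). All indices are 0-based here; R wrappers translate.

namespace {

struct TreeBuf {
  std::vector<int> var, kid0, kid1, leaf_class;
};

double gini_from_counts(const std::vector<int>& cnt, int n) {
  if (n == 0) return 0.0;
  double g = 1.0;
  for (int c : cnt) {
    double f = (double)c / n;
    g -= f * f;
  }
  return g;
}

int majority_class(const std::vector<int>& cnt) {
  int best = 0;
  for (size_t c = 1; c < cnt.size(); ++c)
    if (cnt[c] > cnt[best]) best = (int)c;  // strict: ties keep lowest index
  return best;
}

// Grow one node (recursively) on `rows`; returns node index.
int grow_node(const IntegerMatrix& X, const IntegerVector& y, int nclass,
              int mtry, std::vector<int>& rows, TreeBuf& tb) {
  int p = X.ncol();
  int n = (int)rows.size();
  std::vector<int> cnt(nclass, 0);
  for (int r : rows) cnt[y[r]]++;

  int node = (int)tb.var.size();
  tb.var.push_back(-1);
  tb.kid0.push_back(-1);
  tb.kid1.push_back(-1);
  tb.leaf_class.push_back(majority_class(cnt));

  double parent_gini = gini_from_counts(cnt, n);
  if (parent_gini <= 0.0) return node;  // pure

  // mtry candidate items without replacement (R RNG, seed-reproducible)
  IntegerVector cand = sample(p, std::min(mtry, p), false);  // 1-based

  int best_var = -1;
  double best_impurity = parent_gini - 1e-12;  // require strict reduction
  std::vector<int> cnt0(nclass), cnt1(nclass);
  for (int ci = 0; ci < cand.size(); ++ci) {
    int v = cand[ci] - 1;
    std::fill(cnt0.begin(), cnt0.end(), 0);
    int n0 = 0;
    for (int r : rows) {
      if (X(r, v) == 0) { cnt0[y[r]]++; n0++; }
    }
    int n1 = n - n0;
    if (n0 == 0 || n1 == 0) continue;  // a child would be empty
    for (int c = 0; c < nclass; ++c) cnt1[c] = cnt[c] - cnt0[c];
    double w = (n0 * gini_from_counts(cnt0, n0) +
                n1 * gini_from_counts(cnt1, n1)) / n;
    if (w < best_impurity) {
      best_impurity = w;
      best_var = v;
    }
  }
  if (best_var < 0) return node;  // no admissible impurity-reducing split

  std::vector<int> rows0, rows1;
  rows0.reserve(n); rows1.reserve(n);
  for (int r : rows) (X(r, best_var) == 0 ? rows0 : rows1).push_back(r);
  rows.clear(); rows.shrink_to_fit();

  tb.var[node] = best_var;
  tb.kid0[node] = grow_node(X, y, nclass, mtry, rows0, tb);
  tb.kid1[node] = grow_node(X, y, nclass, mtry, rows1, tb);
  return node;
}

// Unpacked tree arrays, hoisted out of the per-row prediction loop.
struct TreeView {
  IntegerVector var, kid0, kid1, leaf;
  explicit TreeView(const List& tree)
      : var(tree["var"]), kid0(tree["kid0"]), kid1(tree["kid1"]),
        leaf(tree["leaf_class"]) {}
};

int tree_predict_row(const TreeView& tv, const IntegerMatrix& X, int i,
                     int swap_var, const IntegerVector& swapped) {
  int node = 0;
  while (tv.var[node] >= 0) {
    int v = tv.var[node];
    int val = (v == swap_var) ? swapped[i] : X(i, v);
    node = (val == 0) ? tv.kid0[node] : tv.kid1[node];
  }
  return tv.leaf[node];
}

}  // namespace

// [[Rcpp::export]]
List grow_forest_cpp(IntegerMatrix X, IntegerVector y, int nclass, int ntree,
                     int mtry) {
  int n = X.nrow();
  List trees(ntree), boots(ntree);
  for (int t = 0; t < ntree; ++t) {
    IntegerVector bs = sample(n, n, true);  // 1-based bootstrap indices
    std::vector<int> rows(n);
    for (int i = 0; i < n; ++i) rows[i] = bs[i] - 1;
    TreeBuf tb;
    grow_node(X, y, nclass, mtry, rows, tb);
    trees[t] = List::create(_["var"] = wrap(tb.var), _["kid0"] = wrap(tb.kid0),
                            _["kid1"] = wrap(tb.kid1),
                            _["leaf_class"] = wrap(tb.leaf_class));
    boots[t] = bs;
  }
  return List::create(_["trees"] = trees, _["bootstrap"] = boots);
}

// Votes per subject x class; tree t votes for row i only if use(i, t).
// [[Rcpp::export]]
IntegerMatrix forest_votes_cpp(List trees, IntegerMatrix X, int nclass,
                               LogicalMatrix use) {
  int n = X.nrow(), ntree = trees.size();
  IntegerMatrix votes(n, nclass);
  IntegerVector none(0);
  for (int t = 0; t < ntree; ++t) {
    TreeView tv((List)trees[t]);
    for (int i = 0; i < n; ++i) {
      if (!use(i, t)) continue;
      votes(i, tree_predict_row(tv, X, i, -1, none))++;
    }
  }
  return votes;
}

// Fraction of trees in which rows i and j share a terminal node.
// [[Rcpp::export]]
NumericMatrix proximity_cpp(List trees, IntegerMatrix X) {
  int n = X.nrow(), ntree = trees.size();
  NumericMatrix prox(n, n);
  std::vector<int> leaf(n);
  for (int t = 0; t < ntree; ++t) {
    TreeView tv((List)trees[t]);
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (tv.var[node] >= 0)
        node = (X(i, tv.var[node]) == 0) ? tv.kid0[node] : tv.kid1[node];
      leaf[i] = node;
    }
    for (int i = 0; i < n; ++i)
      for (int j = i; j < n; ++j)
        if (leaf[i] == leaf[j]) { prox(i, j) += 1.0; prox(j, i) = prox(i, j); }
  }
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) prox(i, j) /= ntree;
  for (int i = 0; i < n; ++i) prox(i, i) = 1.0;
  return prox;
}

// OOB permutation importance (mean decrease in accuracy), overall and
// per true class. oob(i, t) is TRUE when row i is out-of-bag for tree t.
// [[Rcpp::export]]
List perm_importance_cpp(List trees, IntegerMatrix X, IntegerVector y,
                         int nclass, LogicalMatrix oob) {
  int n = X.nrow(), p = X.ncol(), ntree = trees.size();
  NumericVector overall(p);
  NumericMatrix per_class(nclass, p);
  IntegerVector ntree_class(nclass);  // trees with >=1 OOB case of class c
  IntegerVector none(0);

  for (int t = 0; t < ntree; ++t) {
    TreeView tv((List)trees[t]);
    std::vector<bool> used(p, false);
    for (int k = 0; k < tv.var.size(); ++k)
      if (tv.var[k] >= 0) used[tv.var[k]] = true;

    std::vector<int> orows;
    for (int i = 0; i < n; ++i)
      if (oob(i, t)) orows.push_back(i);
    int m = (int)orows.size();
    if (m == 0) continue;

    std::vector<int> base_ok(nclass, 0), noob(nclass, 0);
    int base_tot = 0;
    for (int i : orows) {
      noob[y[i]]++;
      if (tree_predict_row(tv, X, i, -1, none) == y[i]) {
        base_ok[y[i]]++;
        base_tot++;
      }
    }
    for (int c = 0; c < nclass; ++c)
      if (noob[c] > 0) ntree_class[c]++;

    IntegerVector swapped(n);
    for (int v = 0; v < p; ++v) {
      if (!used[v]) continue;  // unused item: zero decrease by definition
      // permute item v among this tree's OOB rows (R RNG)
      IntegerVector perm = sample(m, m, false);
      for (int k = 0; k < m; ++k)
        swapped[orows[k]] = X(orows[perm[k] - 1], v);
      std::vector<int> perm_ok(nclass, 0);
      int perm_tot = 0;
      for (int i : orows) {
        if (tree_predict_row(tv, X, i, v, swapped) == y[i]) {
          perm_ok[y[i]]++;
          perm_tot++;
        }
      }
      overall[v] += (double)(base_tot - perm_tot) / m;
      for (int c = 0; c < nclass; ++c)
        if (noob[c] > 0)
          per_class(c, v) += (double)(base_ok[c] - perm_ok[c]) / noob[c];
    }
  }
  for (int v = 0; v < p; ++v) {
    overall[v] /= ntree;
    for (int c = 0; c < nclass; ++c)
      if (ntree_class[c] > 0) per_class(c, v) /= ntree_class[c];
  }
  return List::create(_["overall"] = overall, _["per_class"] = per_class);
}
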