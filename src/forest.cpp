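#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Tree nodes are rows of a numeric matrix with columns:
//   0 feature  (0-based attribute index; -1 for a leaf)
//   1 threshold (go left when x[feature] <= threshold)
//   2 left     (0-based node index)
//   3 right    (0-based node index)
//   4 label    (0/1 class index; meaningful at leaves only)

struct Node {
  int feature;
  double threshold;
  int left, right, label;
};

static int majority_label(int n0, int n1) {
  // tie -> class 0, the lexicographically first level
  return (n1 > n0) ? 1 : 0;
}

// Partial Fisher-Yates draw of k distinct values from 0..p-1, sorted
// ascending so candidate features are scanned in a deterministic order.
static std::vector<int> sample_features(int p, int k) {
  std::vector<int> pool(p);
  for (int i = 0; i < p; ++i) pool[i] = i;
  for (int i = 0; i < k; ++i) {
    int j = i + (int)(unif_rand() * (p - i));
    if (j >= p) j = p - 1;
    std::swap(pool[i], pool[j]);
  }
  std::vector<int> out(pool.begin(), pool.begin() + k);
  std::sort(out.begin(), out.end());
  return out;
}

struct SplitChoice {
  bool found;
  int feature;
  double threshold;
};

// Best (attribute, threshold) by weighted Gini impurity of the two children.
// Thresholds are midpoints between consecutive distinct sorted values; ties
// in impurity break to the lowest attribute index, then lowest threshold
// (guaranteed by ascending scan order with strict improvement).
static SplitChoice best_split(const NumericMatrix& X, const IntegerVector& y,
                              const std::vector<int>& rows,
                              const std::vector<int>& feats) {
  SplitChoice best{false, -1, 0.0};
  double best_gini = R_PosInf;
  const int n = (int)rows.size();
  std::vector<std::pair<double, int>> vals(n); // (value, label)

  for (int f : feats) {
    for (int i = 0; i < n; ++i) {
      vals[i] = std::make_pair(X(rows[i], f), y[rows[i]]);
    }
    std::sort(vals.begin(), vals.end());
    int tot1 = 0;
    for (int i = 0; i < n; ++i) tot1 += vals[i].second;
    int left1 = 0;
    for (int i = 0; i < n - 1; ++i) {
      left1 += vals[i].second;
      if (vals[i].first == vals[i + 1].first) continue;
      const int nl = i + 1, nr = n - nl;
      const double pl1 = (double)left1 / nl;
      const double pr1 = (double)(tot1 - left1) / nr;
      const double gini = (nl * 2.0 * pl1 * (1.0 - pl1) +
                           nr * 2.0 * pr1 * (1.0 - pr1)) / n;
      if (gini < best_gini) {
        best_gini = gini;
        best.found = true;
        best.feature = f;
        best.threshold = (vals[i].first + vals[i + 1].first) / 2.0;
      }
    }
  }
  return best;
}

static void grow(const NumericMatrix& X, const IntegerVector& y,
                 std::vector<int> rows, int mtry, int min_node_size,
                 std::vector<Node>& nodes, int node_id) {
  int n0 = 0, n1 = 0;
  for (int r : rows) (y[r] == 1) ? ++n1 : ++n0;
  const int n = (int)rows.size();

  bool make_leaf = (n0 == 0 || n1 == 0 || n <= min_node_size);
  SplitChoice split{false, -1, 0.0};
  if (!make_leaf) {
    split = best_split(X, y, rows, sample_features(X.ncol(), mtry));
    if (!split.found) make_leaf = true; // all candidate attributes constant
  }
  if (make_leaf) {
    nodes[node_id] = {-1, 0.0, -1, -1, majority_label(n0, n1)};
    return;
  }

  std::vector<int> left_rows, right_rows;
  left_rows.reserve(n);
  right_rows.reserve(n);
  for (int r : rows) {
    if (X(r, split.feature) <= split.threshold) left_rows.push_back(r);
    else right_rows.push_back(r);
  }
  rows.clear();
  rows.shrink_to_fit();

  const int left_id = (int)nodes.size();
  nodes.push_back(Node());
  const int right_id = (int)nodes.size();
  nodes.push_back(Node());
  nodes[node_id] = {split.feature, split.threshold, left_id, right_id, -1};
  grow(X, y, std::move(left_rows), mtry, min_node_size, nodes, left_id);
  grow(X, y, std::move(right_rows), mtry, min_node_size, nodes, right_id);
}

static NumericMatrix nodes_to_matrix(const std::vector<Node>& nodes) {
  NumericMatrix m((int)nodes.size(), 5);
  for (int i = 0; i < (int)nodes.size(); ++i) {
    m(i, 0) = nodes[i].feature;
    m(i, 1) = nodes[i].threshold;
    m(i, 2) = nodes[i].left;
    m(i, 3) = nodes[i].right;
    m(i, 4) = nodes[i].label;
  }
  colnames(m) = CharacterVector::create("feature", "threshold", "left",
                                        "right", "label");
  return m;
}

// [[Rcpp::export]]
NumericMatrix build_tree_cpp(NumericMatrix X, IntegerVector y, int mtry,
                             int min_node_size) {
  std::vector<int> rows(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) rows[i] = i;
  std::vector<Node> nodes(1);
  grow(X, y, std::move(rows), mtry, min_node_size, nodes, 0);
  return nodes_to_matrix(nodes);
}

// [[Rcpp::export]]
List fit_forest_cpp(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
                    int min_node_size, bool bootstrap) {
  const int n = X.nrow();
  List trees(n_trees);
  for (int b = 0; b < n_trees; ++b) {
    std::vector<int> rows(n);
    if (bootstrap) {
      for (int i = 0; i < n; ++i) {
        int j = (int)(unif_rand() * n);
        rows[i] = (j >= n) ? n - 1 : j;
      }
    } else {
      for (int i = 0; i < n; ++i) rows[i] = i;
    }
    std::vector<Node> nodes(1);
    grow(X, y, std::move(rows), mtry, min_node_size, nodes, 0);
    trees[b] = nodes_to_matrix(nodes);
  }
  return trees;
}

static int tree_predict_one(const NumericMatrix& tree, const NumericMatrix& X,
                            int row) {
  int node = 0;
  while ((int)tree(node, 0) != -1) {
    node = (X(row, (int)tree(node, 0)) <= tree(node, 1))
               ? (int)tree(node, 2)
               : (int)tree(node, 3);
  }
  return (int)tree(node, 4);
}

// Per-instance vote counts across trees; columns = class 0, class 1.
// [[Rcpp::export]]
IntegerMatrix forest_votes_cpp(List trees, NumericMatrix X) {
  const int m = X.nrow();
  IntegerMatrix votes(m, 2);
  for (int b = 0; b < trees.size(); ++b) {
    NumericMatrix tree = trees[b];
    for (int i = 0; i < m; ++i) {
      ++votes(i, tree_predict_one(tree, X, i));
    }
  }
  return votes;
}
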