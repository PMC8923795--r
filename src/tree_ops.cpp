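#include <Rcpp.h>
using namespace Rcpp;

// Expression-tree nodes are R lists with a fixed field layout:
//   function node: [0] t = 0L, [1] oc (1 '+', 2 '-', 3 '*', 4 protected '/'),
//                  [2] op (printable symbol), [3] kids (list of child nodes)
//   feature node:  [0] t = 1L, [1] ix (1-based column index), [2] feat (name)
//   constant:      [0] t = 2L, [1] val (double)
// Field positions are part of the internal contract with R/tree.R.

static NumericVector ev(const List node, const NumericMatrix X) {
  const int t = as<int>(node[0]);
  const int n = X.nrow();
  if (t == 1) {
    const int ix = as<int>(node[1]) - 1;
    NumericVector out(n);
    for (int i = 0; i < n; ++i) out[i] = X(i, ix);
    return out;
  }
  if (t == 2) {
    return NumericVector(n, as<double>(node[1]));
  }
  const int oc = as<int>(node[1]);
  const List kids = node[3];
  NumericVector a = ev(kids[0], X);
  NumericVector b = ev(kids[1], X);
  NumericVector r(n);
  switch (oc) {
  case 1: for (int i = 0; i < n; ++i) r[i] = a[i] + b[i]; break;
  case 2: for (int i = 0; i < n; ++i) r[i] = a[i] - b[i]; break;
  case 3: for (int i = 0; i < n; ++i) r[i] = a[i] * b[i]; break;
  case 4:
    // protected division: near-zero denominator or non-finite quotient -> 1
    for (int i = 0; i < n; ++i) {
      const double d = b[i];
      if (std::fabs(d) < 1e-9) { r[i] = 1.0; }
      else {
        const double q = a[i] / d;
        r[i] = R_finite(q) ? q : 1.0;
      }
    }
    break;
  default: stop("unknown operator code %d", oc);
  }
  return r;
}

// [[Rcpp::export]]
NumericVector eval_tree_cpp(List root, NumericMatrix X) {
  NumericVector v = ev(root, X);
  // any residual overflow from +/-/* is clamped so outputs are always finite
  for (int i = 0; i < v.size(); ++i) if (!R_finite(v[i])) v[i] = 0.0;
  return v;
}

// [[Rcpp::export]]
int tree_depth_cpp(List node) {
  if (as<int>(node[0]) != 0) return 1;
  const List kids = node[3];
  int d = 0;
  for (int j = 0; j < kids.size(); ++j) {
    const int dj = tree_depth_cpp(kids[j]);
    if (dj > d) d = dj;
  }
  return 1 + d;
}

// [[Rcpp::export]]
int tree_size_cpp(List node) {
  if (as<int>(node[0]) != 0) return 1;
  const List kids = node[3];
  int s = 1;
  for (int j = 0; j < kids.size(); ++j) s += tree_size_cpp(kids[j]);
  return s;
}

static void count_feats(const List node, IntegerVector& counts) {
  const int t = as<int>(node[0]);
  if (t == 1) {
    const int ix = as<int>(node[1]) - 1;
    if (ix < 0 || ix >= counts.size()) stop("feature index out of range");
    counts[ix] += 1;
    return;
  }
  if (t == 2) return;
  const List kids = node[3];
  for (int j = 0; j < kids.size(); ++j) count_feats(kids[j], counts);
}

// Per-feature terminal occurrence counts over the bound feature set.
// [[Rcpp::export]]
IntegerVector feature_counts_cpp(List node, int n_features) {
  IntegerVector counts(n_features);
  count_feats(node, counts);
  return counts;
}
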