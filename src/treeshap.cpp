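#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact interventional Shapley values for an additive tree ensemble.
//
// For one tree, explicand x and background row z, the coalition game is
//   v(S) = tree(x restricted to S, z elsewhere).
// Each leaf is reachable under coalition S iff every split on its path is
// satisfied by the source the coalition dictates.  Collapsing duplicate
// split features on the path, a leaf contributes val * 1[A subset of S,
// B disjoint from S], where A are path features x satisfies but z violates
// and B the reverse; features violated by both make the leaf unreachable
// for every S.  The Shapley value of that indicator game is closed-form:
//   phi_j = (a-1)! b! / (a+b)!      for j in A
//   phi_j = -a! (b-1)! / (a+b)!     for j in B
// so one DFS per (tree, x, z) accumulates exact attributions.  Averaging
// over background rows and trees gives interventional SHAP values whose
// sum is exactly f(x) - mean_z f(z) (efficiency).

namespace {

struct Tree {
  std::vector<int> left, right, var;   // var = -1 at leaves
  std::vector<double> split, value;
};

struct Walker {
  const Tree* tr;
  const double* x;
  const double* z;
  int p;
  std::vector<int> xfail, zfail, tcount;
  std::vector<int> touched;
  const std::vector<std::vector<double> >* wA;
  const std::vector<std::vector<double> >* wB;
  double* phi;      // length p accumulator
  double fx, fz;    // accumulated tree value for full / empty coalition

  void leaf(double val) {
    int a = 0, b = 0;
    for (size_t t = 0; t < touched.size(); ++t) {
      int j = touched[t];
      bool xf = xfail[j] > 0, zf = zfail[j] > 0;
      if (xf && zf) return;            // unreachable under any coalition
      if (!xf && zf) ++a;
      else if (xf && !zf) ++b;
    }
    if (a == 0) fx += val;             // reachable by pure x path
    if (b == 0) fz += val;             // reachable by pure z path
    if (a == 0 && b == 0) return;      // constant part, no attribution
    double wa = (a > 0) ? (*wA)[a][b] * val : 0.0;
    double wb = (b > 0) ? (*wB)[a][b] * val : 0.0;
    for (size_t t = 0; t < touched.size(); ++t) {
      int j = touched[t];
      bool xf = xfail[j] > 0, zf = zfail[j] > 0;
      if (!xf && zf) phi[j] += wa;
      else if (xf && !zf) phi[j] += wb;
    }
  }

  void descend(int node) {
    int j = tr->var[node];
    if (j < 0) { leaf(tr->value[node]); return; }
    bool xleft = x[j] <= tr->split[node];
    bool zleft = z[j] <= tr->split[node];
    // left branch
    step(tr->left[node], j, !xleft, !zleft);
    // right branch
    step(tr->right[node], j, xleft, zleft);
  }

  void step(int child, int j, bool xviol, bool zviol) {
    if ((xfail[j] + (int)xviol) > 0 && (zfail[j] + (int)zviol) > 0)
      return;  // subtree unreachable for every coalition
    if (tcount[j]++ == 0) touched.push_back(j);
    xfail[j] += xviol; zfail[j] += zviol;
    descend(child);
    xfail[j] -= xviol; zfail[j] -= zviol;
    if (--tcount[j] == 0) touched.pop_back();
  }
};

}  // namespace

// trees: list of matrices with columns (left, right, var, split, value),
// 0-based child/variable indices, var = -1 for terminal nodes.
// [[Rcpp::export]]
List treeshap_interventional(NumericMatrix X, NumericMatrix Z, List trees) {
  const int n = X.nrow(), p = X.ncol(), B = Z.nrow(), T = trees.size();
  if (Z.ncol() != p) stop("background and explicand dimension mismatch");

  std::vector<Tree> forest(T);
  int maxdepth = 2;
  for (int t = 0; t < T; ++t) {
    NumericMatrix m = trees[t];
    int nn = m.nrow();
    Tree& tr = forest[t];
    tr.left.resize(nn); tr.right.resize(nn); tr.var.resize(nn);
    tr.split.resize(nn); tr.value.resize(nn);
    for (int i = 0; i < nn; ++i) {
      tr.left[i] = (int)m(i, 0); tr.right[i] = (int)m(i, 1);
      tr.var[i] = (int)m(i, 2); tr.split[i] = m(i, 3); tr.value[i] = m(i, 4);
    }
    // tree depth bounds |A| + |B| at any leaf
    std::vector<int> depth(nn, 0);
    for (int i = 0; i < nn; ++i) {
      if (tr.var[i] >= 0) {
        depth[tr.left[i]] = depth[i] + 1;   // children stored after parents
        depth[tr.right[i]] = depth[i] + 1;
      }
      if (depth[i] + 2 > maxdepth) maxdepth = depth[i] + 2;
    }
  }

  // closed-form indicator-game weights, via log-gamma for stability
  std::vector<std::vector<double> > wA(maxdepth + 1,
                                       std::vector<double>(maxdepth + 1, 0.0));
  std::vector<std::vector<double> > wB = wA;
  for (int a = 0; a <= maxdepth; ++a)
    for (int b = 0; a + b <= maxdepth; ++b) {
      if (a > 0)
        wA[a][b] = std::exp(std::lgamma((double)a) + std::lgamma((double)b + 1)
                            - std::lgamma((double)(a + b) + 1));
      if (b > 0)
        wB[a][b] = -std::exp(std::lgamma((double)a + 1) + std::lgamma((double)b)
                             - std::lgamma((double)(a + b) + 1));
    }

  NumericMatrix phi(n, p);
  std::vector<double> acc(p);
  Walker w;
  w.p = p; w.wA = &wA; w.wB = &wB;
  w.xfail.assign(p, 0); w.zfail.assign(p, 0); w.tcount.assign(p, 0);

  std::vector<double> xrow(p), zrow(p);
  for (int i = 0; i < n; ++i) {
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int j = 0; j < p; ++j) xrow[j] = X(i, j);
    w.x = &xrow[0]; w.phi = &acc[0];
    for (int bz = 0; bz < B; ++bz) {
      for (int j = 0; j < p; ++j) zrow[j] = Z(bz, j);
      w.z = &zrow[0];
      for (int t = 0; t < T; ++t) {
        w.tr = &forest[t];
        w.fx = 0.0; w.fz = 0.0;
        w.descend(0);
      }
    }
    const double scale = 1.0 / ((double)B * (double)T);
    for (int j = 0; j < p; ++j) phi(i, j) = acc[j] * scale;
    if (i % 32 == 0) Rcpp::checkUserInterrupt();
  }

  // ensemble prediction for background rows (for the base value)
  NumericVector fz(B);
  for (int bz = 0; bz < B; ++bz) {
    double s = 0.0;
    for (int t = 0; t < T; ++t) {
      const Tree& tr = forest[t];
      int node = 0;
      while (tr.var[node] >= 0)
        node = (Z(bz, tr.var[node]) <= tr.split[node]) ? tr.left[node]
                                                       : tr.right[node];
      s += tr.value[node];
    }
    fz[bz] = s / (double)T;
  }

  return List::create(Named("phi") = phi, Named("fz") = fz);
}

// Plain ensemble prediction by tree traversal (used to verify that the
// canonical tree encoding reproduces the fitted model's predictions).
// [[Rcpp::export]]
NumericVector treepredict(NumericMatrix X, List trees) {
  const int n = X.nrow(), T = trees.size();
  std::vector<Tree> forest(T);
  for (int t = 0; t < T; ++t) {
    NumericMatrix m = trees[t];
    int nn = m.nrow();
    Tree& tr = forest[t];
    tr.left.resize(nn); tr.right.resize(nn); tr.var.resize(nn);
    tr.split.resize(nn); tr.value.resize(nn);
    for (int i = 0; i < nn; ++i) {
      tr.left[i] = (int)m(i, 0); tr.right[i] = (int)m(i, 1);
      tr.var[i] = (int)m(i, 2); tr.split[i] = m(i, 3); tr.value[i] = m(i, 4);
    }
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int t = 0; t < T; ++t) {
      const Tree& tr = forest[t];
      int node = 0;
      while (tr.var[node] >= 0)
        node = (X(i, tr.var[node]) <= tr.split[node]) ? tr.left[node]
                                                      : tr.right[node];
      s += tr.value[node];
    }
    out[i] = s / (double)T;
  }
  return out;
}
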