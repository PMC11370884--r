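#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Pruning likelihood for the pure-loss gene-content model.
//
// Root content size N ~ Poisson(lambda); each of the N ancestral elements
// survives every branch b independently with probability s_b; a node's
// count is the number of elements surviving the path from the root. The
// child-count transition given a parent count m is Binomial(m, s_b), so a
// standard postorder (pruning) pass over counts 0..nmax yields the exact
// likelihood, with the Poisson root prior truncated at nmax.
//
// counts:    P x ntip matrix of observed leaf counts
// postorder: node ids (1-based), children listed before parents
// parent:    per-node parent id (0 for the root)
// nchild:    per-node number of children
// surv:      per-node survival probability of the branch above (root unused)
// leaf_col:  per-node 0-based column into counts, or -1 for internal nodes
// [[Rcpp::export]]
NumericVector pl_loglik_cpp(IntegerMatrix counts, IntegerVector postorder,
                            IntegerVector parent, IntegerVector nchild,
                            NumericVector surv, IntegerVector leaf_col,
                            double lambda, int nmax) {
  const int P = counts.nrow();
  const int nv = parent.size();
  const int K = nmax + 1;

  // per-node binomial transition tables B_v[m*K + k] = P(child=k | parent=m)
  std::vector< std::vector<double> > B(nv);
  for (int v = 0; v < nv; ++v) {
    if (parent[v] == 0) continue;  // root has no branch above
    B[v].assign((size_t)K * K, 0.0);
    double s = surv[v];
    for (int m = 0; m < K; ++m)
      for (int k = 0; k <= m; ++k)
        B[v][(size_t)m * K + k] = R::dbinom(k, m, s, 0);
  }

  std::vector<double> prior(K);
  for (int m = 0; m < K; ++m) prior[m] = R::dpois(m, lambda, 0);

  NumericVector out(P);
  std::vector< std::vector<double> > L(nv, std::vector<double>(K));
  std::vector<double> M(K);

  for (int p = 0; p < P; ++p) {
    double acc = 0.0;   // accumulated log scaling
    bool impossible = false;
    for (int i = 0; i < nv && !impossible; ++i) {
      int v = postorder[i] - 1;
      if (leaf_col[v] >= 0) {
        int obs = counts(p, leaf_col[v]);
        std::fill(L[v].begin(), L[v].end(), 0.0);
        if (obs > nmax) { impossible = true; break; }
        L[v][obs] = 1.0;
      } else {
        std::fill(L[v].begin(), L[v].end(), 1.0);
        // children were already visited; find them by parent pointers
        for (int c = 0; c < nv; ++c) {
          if (parent[c] - 1 != v) continue;
          const std::vector<double>& Bc = B[c];
          for (int m = 0; m < K; ++m) {
            double acc_m = 0.0;
            const double* row = &Bc[(size_t)m * K];
            const double* Lc = &L[c][0];
            for (int k = 0; k <= m; ++k) acc_m += row[k] * Lc[k];
            M[m] = acc_m;
          }
          for (int m = 0; m < K; ++m) L[v][m] *= M[m];
        }
        double mx = 0.0;
        for (int m = 0; m < K; ++m) if (L[v][m] > mx) mx = L[v][m];
        if (mx <= 0.0) { impossible = true; break; }
        for (int m = 0; m < K; ++m) L[v][m] /= mx;
        acc += std::log(mx);
      }
    }
    if (impossible) { out[p] = R_NegInf; continue; }
    int root = postorder[nv - 1] - 1;
    double lik = 0.0;
    for (int m = 0; m < K; ++m) lik += prior[m] * L[root][m];
    out[p] = (lik > 0.0) ? std::log(lik) + acc : R_NegInf;
  }
  return out;
}
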