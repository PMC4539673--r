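// Felsenstein pruning over sense-codon states with a reversible GY94-style
// generator. The eigen systems of the (possibly branch-specific) generators
// are prepared in R; this kernel builds per-branch transition matrices and
// accumulates the log-likelihood over compressed site patterns.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// P(t) = D^{-1/2} V exp(L t) V' D^{1/2} for Q = D^{-1/2} B D^{1/2},
// B symmetric with eigen decomposition (V, L), D = diag(pi).
static mat transMat(const mat& V, const vec& lam, const vec& sqpi, double t) {
  mat P = V * diagmat(exp(lam * t)) * V.t();
  P.each_col() /= sqpi;   // row scaling 1/sqrt(pi_i)
  P.each_row() %= sqpi.t();  // column scaling sqrt(pi_j)
  P.elem(find(P < 0)).zeros();
  return P;
}

// [[Rcpp::export(name = ".codonPruningCpp")]]
double codonPruningCpp(const arma::imat& tipState,  // ntip x npat, 1-based states
                       const arma::vec& weights,    // npat
                       const arma::imat& edge,      // nedge x 2 (parent, child), 1-based, postorder
                       const arma::vec& edgeLen,
                       const arma::ivec& eigIdx,    // per-edge eigen-system index, 1-based
                       const arma::cube& V,         // ns x ns x K
                       const arma::mat& lambda,     // ns x K
                       const arma::vec& pi,
                       int nNode, int root) {
  const uword ns = pi.n_elem;
  const uword npat = tipState.n_cols;
  const uword ntip = tipState.n_rows;
  vec sqpi = sqrt(pi);

  std::vector<mat> L(nNode + 1);
  std::vector<bool> init(nNode + 1, false);

  for (uword e = 0; e < edge.n_rows; ++e) {
    int par = edge(e, 0), ch = edge(e, 1);
    int k = eigIdx(e) - 1;
    mat P = transMat(V.slice(k), lambda.col(k), sqpi, edgeLen(e));
    mat msg(ns, npat);
    if ((uword)ch <= ntip) {
      for (uword p = 0; p < npat; ++p)
        msg.col(p) = P.col(tipState(ch - 1, p) - 1);
    } else {
      msg = P * L[ch];
    }
    if (!init[par]) { L[par] = msg; init[par] = true; }
    else L[par] %= msg;
  }

  double lnL = 0.0;
  const mat& Lr = L[root];
  for (uword p = 0; p < npat; ++p) {
    double lik = dot(pi, Lr.col(p));
    lnL += weights(p) * std::log(lik);
  }
  return lnL;
}

// Conditional likelihoods for marginal ancestral reconstruction: returns,
// for each node, the matrix of partials from the subtree below it, plus the
// per-edge transition matrices (same traversal as the likelihood).
// [[Rcpp::export(name = ".codonPartialsCpp")]]
Rcpp::List codonPartialsCpp(const arma::imat& tipState,
                            const arma::imat& edge,
                            const arma::vec& edgeLen,
                            const arma::ivec& eigIdx,
                            const arma::cube& V,
                            const arma::mat& lambda,
                            const arma::vec& pi,
                            int nNode) {
  const uword ns = pi.n_elem;
  const uword npat = tipState.n_cols;
  const uword ntip = tipState.n_rows;
  vec sqpi = sqrt(pi);

  Rcpp::List Pmats(edge.n_rows);
  std::vector<mat> L(nNode + 1);
  std::vector<bool> init(nNode + 1, false);

  for (uword e = 0; e < edge.n_rows; ++e) {
    int par = edge(e, 0), ch = edge(e, 1);
    int k = eigIdx(e) - 1;
    mat P = transMat(V.slice(k), lambda.col(k), sqpi, edgeLen(e));
    Pmats[e] = P;
    mat msg(ns, npat);
    if ((uword)ch <= ntip) {
      for (uword p = 0; p < npat; ++p)
        msg.col(p) = P.col(tipState(ch - 1, p) - 1);
    } else {
      msg = P * L[ch];
    }
    if (!init[par]) { L[par] = msg; init[par] = true; }
    else L[par] %= msg;
  }

  Rcpp::List out(nNode + 1);
  for (int v = 1; v <= nNode; ++v)
    if (init[v]) out[v] = L[v];
  return Rcpp::List::create(Rcpp::Named("partials") = out,
                            Rcpp::Named("P") = Pmats);
}
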