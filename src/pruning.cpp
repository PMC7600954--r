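// Felsenstein pruning log-likelihood, matrix-formulated: site patterns are
// columns, so the per-branch propagation P %*% L is a 4 x npat GEMM and the
// per-node rescaling is a column-wise max. GTR+Gamma+I with equal-weight
// gamma categories and an invariant-site class.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// tipstates : ntip x npat, states 0..3, 4 = missing
// weights   : pattern weights
// nodes     : nnode x 5 matrix, one row per internal node in postorder
//             (children-before-parent): node id, child1, child2, edge1,
//             edge2 (1-based; edge indices address rows of `elen`)
// elen      : expected substitutions per edge (rate x time span)
// A, lam, B : eigendecomposition with P(t) = A diag(exp(lam t)) B
// [[Rcpp::export]]
double pruning_loglik_cpp(const IntegerMatrix tipstates,
                          const NumericVector weights,
                          const IntegerMatrix nodes,
                          const NumericVector elen,
                          const arma::mat& A, const arma::vec& lam,
                          const arma::mat& B,
                          const arma::vec& freqs, const arma::vec& catrates,
                          double pinv, const IntegerVector compat) {
  const arma::uword ntip = tipstates.nrow();
  const arma::uword npat = tipstates.ncol();
  const arma::uword nnode = nodes.nrow();
  const arma::uword ncat = catrates.n_elem;
  const double catw = 1.0 / ncat;
  const arma::uword nedge = elen.size();

  // P columns per edge per category, with a 5th all-ones column so that a
  // missing tip state gathers a vector of ones.
  std::vector<arma::mat> P(nedge * ncat);
  for (arma::uword e = 0; e < nedge; e++) {
    for (arma::uword c = 0; c < ncat; c++) {
      arma::mat M = A * arma::diagmat(arma::exp(lam * (elen[e] * catrates[c]))) * B;
      M.clamp(0.0, arma::datum::inf);
      M.each_col() /= arma::sum(M, 1);   // renormalise rows
      arma::mat Mc(4, 5);
      Mc.cols(0, 3) = M;
      Mc.col(4).ones();
      P[e * ncat + c] = Mc;
    }
  }

  // partial likelihoods: one 4 x npat matrix per internal node per category
  std::vector<arma::mat> L(nnode * ncat);
  arma::rowvec logscale(npat, arma::fill::zeros);
  arma::urowvec tipidx(npat);

  auto child_contrib = [&](int child, arma::uword e, arma::uword c,
                           arma::mat& out) {
    if ((arma::uword)child <= ntip) {
      for (arma::uword p = 0; p < npat; p++)
        tipidx[p] = (arma::uword)tipstates(child - 1, p);
      out = P[e * ncat + c].cols(tipidx);
    } else {
      out = P[e * ncat + c].cols(0, 3) * L[(child - ntip - 1) * ncat + c];
    }
  };

  arma::mat tmp1(4, npat), tmp2(4, npat);
  for (arma::uword v = 0; v < nnode; v++) {
    const int me = nodes(v, 0), k1 = nodes(v, 1), k2 = nodes(v, 2);
    const arma::uword e1 = nodes(v, 3) - 1, e2 = nodes(v, 4) - 1;
    const arma::uword base = (me - ntip - 1) * ncat;
    arma::rowvec m(npat, arma::fill::zeros);
    for (arma::uword c = 0; c < ncat; c++) {
      child_contrib(k1, e1, c, tmp1);
      child_contrib(k2, e2, c, tmp2);
      L[base + c] = tmp1 % tmp2;
      m = arma::max(m, arma::max(L[base + c], 0));
    }
    if (m.min() <= 0.0) return R_NegInf;
    arma::rowvec inv_m = 1.0 / m;
    for (arma::uword c = 0; c < ncat; c++) L[base + c].each_row() %= inv_m;
    logscale += arma::log(m);
  }

  // root is the last processed node
  const arma::uword root_base = (nodes(nnode - 1, 0) - ntip - 1) * ncat;
  arma::rowvec sl(npat, arma::fill::zeros);
  for (arma::uword c = 0; c < ncat; c++)
    sl += catw * (freqs.t() * L[root_base + c]);

  double ll = 0.0;
  const double log1mp = (pinv < 1.0) ? std::log(1.0 - pinv) : R_NegInf;
  for (arma::uword p = 0; p < npat; p++) {
    double site_ll;
    if (pinv > 0.0) {
      double invlik = 0.0;
      const int mask = compat[p];
      for (int s = 0; s < 4; s++)
        if (mask & (1 << s)) invlik += freqs[s];
      invlik *= pinv;
      double var_log = (sl[p] > 0.0) ? log1mp + std::log(sl[p]) + logscale[p]
                                     : R_NegInf;
      double inv_log = (invlik > 0.0) ? std::log(invlik) : R_NegInf;
      if (var_log == R_NegInf && inv_log == R_NegInf) return R_NegInf;
      double mx = (var_log > inv_log) ? var_log : inv_log;
      site_ll = mx + std::log(std::exp(var_log - mx) + std::exp(inv_log - mx));
    } else {
      if (sl[p] <= 0.0) return R_NegInf;
      site_ll = std::log(sl[p]) + logscale[p];
    }
    ll += weights[p] * site_ll;
  }
  return ll;
}
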