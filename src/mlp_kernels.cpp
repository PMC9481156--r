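// Dense MLP forward/backward kernels. Hot path of training: fused affine +
// ReLU + inverted dropout, with caches for the reverse sweep. Dropout draws
// use R's RNG so runs stay reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
List mlp_fwd_cpp(List W, List b, const arma::mat& X, double p, bool training,
                 bool keep) {
  int nl = W.size() - 1;
  List ins(nl + 1), mask(nl);
  arma::mat A = X;
  RNGScope scope;
  for (int j = 0; j < nl; ++j) {
    if (keep) ins[j] = A;
    arma::mat Wj = as<arma::mat>(W[j]);
    arma::rowvec bj = as<arma::rowvec>(b[j]);
    arma::mat Z = A * Wj;
    Z.each_row() += bj;
    arma::mat M(Z.n_rows, Z.n_cols);
    if (training && p > 0) {
      double scale = 1.0 / (1.0 - p);
      for (arma::uword k = 0; k < Z.n_elem; ++k)
        M[k] = (Z[k] > 0 && unif_rand() >= p) ? scale : 0.0;
    } else {
      for (arma::uword k = 0; k < Z.n_elem; ++k) M[k] = Z[k] > 0 ? 1.0 : 0.0;
    }
    A = Z % M;
    if (keep) mask[j] = M;
  }
  if (keep) ins[nl] = A;
  arma::mat Wo = as<arma::mat>(W[nl]);
  arma::rowvec bo = as<arma::rowvec>(b[nl]);
  arma::mat out = A * Wo;
  out.each_row() += bo;
  if (keep)
    return List::create(_["out"] = out, _["ins"] = ins, _["mask"] = mask);
  return List::create(_["out"] = out);
}

// [[Rcpp::export]]
List mlp_bwd_cpp(List W, List ins, List mask, const arma::mat& gout) {
  int nl = W.size() - 1;
  List gW(nl + 1), gb(nl + 1);
  arma::mat g = gout;
  {
    arma::mat Ain = as<arma::mat>(ins[nl]);
    gW[nl] = Ain.t() * g;
    gb[nl] = arma::sum(g, 0);
    arma::mat Wo = as<arma::mat>(W[nl]);
    g = g * Wo.t();
  }
  for (int j = nl - 1; j >= 0; --j) {
    arma::mat M = as<arma::mat>(mask[j]);
    g %= M;
    arma::mat Ain = as<arma::mat>(ins[j]);
    gW[j] = Ain.t() * g;
    gb[j] = arma::sum(g, 0);
    arma::mat Wj = as<arma::mat>(W[j]);
    g = g * Wj.t();
  }
  return List::create(_["gin"] = g, _["gW"] = gW, _["gb"] = gb);
}

// One Adam step over the nested parameter/gradient/moment lists (same
// recursive shape); returns updated copies.
static void adam_walk(List p, List g, List m, List v,
                      double lr, double b1, double b2, double eps,
                      double c1, double c2) {
  int n = p.size();
  for (int i = 0; i < n; ++i) {
    SEXP pi = p[i];
    if (TYPEOF(pi) == VECSXP) {
      adam_walk(p[i], g[i], m[i], v[i], lr, b1, b2, eps, c1, c2);
    } else {
      NumericVector pv = clone(as<NumericVector>(p[i]));
      NumericVector gv = g[i];
      NumericVector mv = clone(as<NumericVector>(m[i]));
      NumericVector vv = clone(as<NumericVector>(v[i]));
      int k = pv.size();
      for (int q = 0; q < k; ++q) {
        mv[q] = b1 * mv[q] + (1 - b1) * gv[q];
        vv[q] = b2 * vv[q] + (1 - b2) * gv[q] * gv[q];
        pv[q] -= lr * (mv[q] / c1) / (std::sqrt(vv[q] / c2) + eps);
      }
      p[i] = pv; m[i] = mv; v[i] = vv;
    }
  }
}

// [[Rcpp::export]]
List adam_step_cpp(List params, List grads, List m, List v, double lr,
                   double beta1, double beta2, double eps, int t) {
  List p = clone(params), mm = clone(m), vv = clone(v);
  double c1 = 1 - std::pow(beta1, t), c2 = 1 - std::pow(beta2, t);
  adam_walk(p, grads, mm, vv, lr, beta1, beta2, eps, c1, c2);
  return List::create(_["p"] = p, _["m"] = mm, _["v"] = vv);
}
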