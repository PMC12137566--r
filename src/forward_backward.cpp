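#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Scaled forward-backward for a hidden Markov chain with state-conditional
// log emission densities. `reset` marks positions where the chain is
// re-initialised from `init` instead of transitioning from the previous
// step (session boundaries); position 0 is always treated as a reset.
//
// loglik: T x S log emission densities
// trans:  S x S row-stochastic transition matrix
// init:   length-S initial state distribution
// reset:  integer vector of length T (0/1)
// store_xi: also return the full (T-1) x S x S pairwise posterior cube
//
// Returns gamma (T x S smoothed posteriors), xi_sum (S x S expected
// transition counts, excluding pairs that straddle a reset), and the exact
// marginal log-likelihood.
// [[Rcpp::export]]
Rcpp::List fb_smooth_cpp(const arma::mat& loglik, const arma::mat& trans,
                         const arma::vec& init, const arma::ivec& reset,
                         const bool store_xi) {
  const uword T = loglik.n_rows, S = loglik.n_cols;

  // per-row max subtracted before exponentiation for numerical stability
  vec m = max(loglik, 1);
  mat lik = exp(loglik.each_col() - m);

  mat alpha(T, S), beta(T, S);
  vec cnorm(T);

  rowvec pred(S);
  for (uword t = 0; t < T; ++t) {
    if (t == 0 || reset[t] != 0) {
      pred = init.t();
    } else {
      pred = alpha.row(t - 1) * trans;
    }
    rowvec a = pred % lik.row(t);
    cnorm[t] = accu(a);
    alpha.row(t) = a / cnorm[t];
  }
  double ll = accu(log(cnorm)) + accu(m);

  beta.row(T - 1).ones();
  for (uword t = T - 1; t-- > 0;) {
    if (reset[t + 1] != 0) {
      beta.row(t).ones();
    } else {
      colvec tmp = (lik.row(t + 1) % beta.row(t + 1)).t();
      beta.row(t) = (trans * tmp).t() / cnorm[t + 1];
    }
  }

  mat gamma = alpha % beta;
  gamma.each_col() /= sum(gamma, 1);  // guard against rounding drift

  mat xi_sum(S, S, fill::zeros);
  cube xi;
  if (store_xi && T > 1) xi.set_size(S, S, T - 1);
  for (uword t = 0; t + 1 < T; ++t) {
    if (reset[t + 1] != 0) {
      if (store_xi) xi.slice(t).zeros();
      continue;
    }
    mat x = (alpha.row(t).t() * (lik.row(t + 1) % beta.row(t + 1))) % trans /
            cnorm[t + 1];
    xi_sum += x;
    if (store_xi) xi.slice(t) = x;
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("gamma") = gamma, Rcpp::Named("xi_sum") = xi_sum,
      Rcpp::Named("loglik") = ll);
  if (store_xi) out["xi"] = xi;
  return out;
}
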