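#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Generalized KL divergence D(V || WH) with 0*log(0) := 0 and WH floored
// at eps, plus alpha * sum over unordered conflicting bin pairs (i,j) of
// (W W^T)_{ij}. C is the symmetric 0/1 conflict matrix, so the unordered
// pair sum equals 0.5 * accu(C % (W W^T)).
static double objective_cpp(const mat& V, const mat& W, const mat& H,
                            const mat& C, double alpha, double eps) {
  mat WH = W * H;
  WH.transform([eps](double x) { return x < eps ? eps : x; });
  double d = 0.0;
  for (uword j = 0; j < V.n_cols; ++j) {
    for (uword i = 0; i < V.n_rows; ++i) {
      double v = V(i, j), wh = WH(i, j);
      if (v > 0.0) d += v * std::log(v / wh) - v + wh;
      else d += wh;
    }
  }
  if (alpha > 0.0 && C.n_rows == W.n_rows)
    d += 0.5 * alpha * accu(C % (W * W.t()));
  return d;
}

// [[Rcpp::export(name = ".nmf_objective_cpp")]]
double nmf_objective_cpp(const arma::mat& V, const arma::mat& W,
                         const arma::mat& H, const arma::mat& C,
                         double alpha, double eps) {
  return objective_cpp(V, W, H, C, alpha, eps);
}

// Multiplicative updates for the penalized KL objective.
//   H_aj <- H_aj *  sum_i W_ia V_ij/(WH)_ij / sum_i W_ia
//   W_ia <- W_ia * (sum_j H_aj V_ij/(WH)_ij) / (sum_j H_aj + alpha (C W)_ia)
// The penalty gradient alpha*(C W) enters the denominator only (C, W >= 0),
// which preserves non-negativity and descent by the usual
// majorize-minimize argument. Stops when the relative objective change over
// a trailing window drops below tol, or at max_iter.
// trace_every > 1 evaluates the objective (and hence the convergence
// check) only every trace_every-th iteration — a cheaper mode for fits
// whose trace is not inspected (e.g. rank scoring); the returned trace
// then holds one value per evaluation.
// [[Rcpp::export(name = ".nmf_fit_cpp")]]
Rcpp::List nmf_fit_cpp(const arma::mat& V, arma::mat W, arma::mat H,
                       const arma::mat& C, double alpha, int max_iter,
                       double tol, double eps, int window,
                       int trace_every = 1) {
  std::vector<double> trace;
  trace.reserve(max_iter / trace_every + 2);
  trace.push_back(objective_cpp(V, W, H, C, alpha, eps));

  const bool pen = alpha > 0.0 && C.n_rows == W.n_rows;
  mat WH, Q;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    // H update
    WH = W * H;
    WH.transform([eps](double x) { return x < eps ? eps : x; });
    Q = V / WH;
    colvec wsum = sum(W, 0).t();
    wsum.transform([eps](double x) { return x < eps ? eps : x; });
    mat numH = W.t() * Q;
    numH.each_col() /= wsum;
    H %= numH;

    // W update
    WH = W * H;
    WH.transform([eps](double x) { return x < eps ? eps : x; });
    Q = V / WH;
    colvec hsum = sum(H, 1);
    mat denom = repmat(hsum.t(), W.n_rows, 1);
    if (pen) denom += alpha * (C * W);
    denom.transform([eps](double x) { return x < eps ? eps : x; });
    W %= (Q * H.t()) / denom;

    if (it % trace_every == 0 || it == max_iter) {
      double d = objective_cpp(V, W, H, C, alpha, eps);
      trace.push_back(d);
      int k = (int)trace.size() - 1;
      int back = std::max(1, window / trace_every);
      if (k >= back) {
        double prev = trace[k - back];
        double ref = std::max(std::abs(prev), eps);
        if (std::abs(prev - d) / ref < tol) break;
      }
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("W") = W, Rcpp::Named("H") = H,
    Rcpp::Named("objective_trace") =
        Rcpp::NumericVector(trace.begin(), trace.end()),
    Rcpp::Named("iterations") = std::min(it, max_iter));
}
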