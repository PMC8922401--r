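// Multi-head self-attention inner loops.
//
// The R code stacks a batch of B sequences of length T as a (B*T) x W
// matrix; attention is the only operation that cannot be expressed as a
// few large BLAS calls, so its per-sequence, per-head loops live here.
// Softmax rows use the max-subtraction form; padding positions are
// excluded as keys by forcing their scores to -inf before the softmax.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Forward: returns the attended output O ((B*T) x W) and the attention
// probabilities A as a (T x T x B*H) cube (slice index b*H + h).
// [[Rcpp::export]]
Rcpp::List mha_forward_cpp(const arma::mat& Q, const arma::mat& K, const arma::mat& V,
                           const Rcpp::LogicalVector& pad, int B, int T,
                           int H) {
  const int W = Q.n_cols;
  const int dh = W / H;
  const double scale = 1.0 / std::sqrt((double) dh);
  mat O(Q.n_rows, W, fill::zeros);
  cube A(T, T, (uword)(B * H), fill::zeros);
  for (int b = 0; b < B; ++b) {
    const uword r0 = (uword) b * T;
    const uword r1 = r0 + T - 1;
    bool any_key = false;
    for (int j = 0; j < T; ++j) {
      if (!pad[b * T + j]) { any_key = true; break; }
    }
    if (!any_key) continue;            // all-padding sequence: zero output
    for (int h = 0; h < H; ++h) {
      const uword c0 = (uword) h * dh;
      const uword c1 = c0 + dh - 1;
      mat S = Q.submat(r0, c0, r1, c1) * K.submat(r0, c0, r1, c1).t();
      S *= scale;
      for (int j = 0; j < T; ++j) {
        if (pad[b * T + j]) S.col(j).fill(-datum::inf);
      }
      // row softmax with max subtraction
      for (int i = 0; i < T; ++i) {
        rowvec r = S.row(i);
        double m = r.max();
        r = exp(r - m);
        S.row(i) = r / accu(r);
      }
      A.slice((uword)(b * H + h)) = S;
      O.submat(r0, c0, r1, c1) = S * V.submat(r0, c0, r1, c1);
    }
  }
  return Rcpp::List::create(Rcpp::Named("O") = O, Rcpp::Named("A") = A);
}

// Backward: given dO and the cached A, Q, K, V, accumulate dQ, dK, dV.
// [[Rcpp::export]]
Rcpp::List mha_backward_cpp(const arma::mat& dO, const arma::cube& A, const arma::mat& Q,
                            const arma::mat& K, const arma::mat& V, int B, int T,
                            int H) {
  const int W = Q.n_cols;
  const int dh = W / H;
  const double scale = 1.0 / std::sqrt((double) dh);
  mat dQ(Q.n_rows, W, fill::zeros);
  mat dK(Q.n_rows, W, fill::zeros);
  mat dV(Q.n_rows, W, fill::zeros);
  for (int b = 0; b < B; ++b) {
    const uword r0 = (uword) b * T;
    const uword r1 = r0 + T - 1;
    for (int h = 0; h < H; ++h) {
      const uword c0 = (uword) h * dh;
      const uword c1 = c0 + dh - 1;
      const arma::mat& Ab = A.slice((uword)(b * H + h));
      mat dOb = dO.submat(r0, c0, r1, c1);
      mat dA = dOb * V.submat(r0, c0, r1, c1).t();
      dV.submat(r0, c0, r1, c1) = Ab.t() * dOb;
      // softmax backward: dS = A * (dA - rowsum(dA * A))
      mat dS = Ab % (dA.each_col() - sum(dA % Ab, 1));
      dQ.submat(r0, c0, r1, c1) = scale * (dS * K.submat(r0, c0, r1, c1));
      dK.submat(r0, c0, r1, c1) = scale * (dS.t() * Q.submat(r0, c0, r1, c1));
    }
  }
  return Rcpp::List::create(Rcpp::Named("dQ") = dQ,
                            Rcpp::Named("dK") = dK,
                            Rcpp::Named("dV") = dV);
}

// ---- small elementwise/row helpers (R-allocation-free hot paths) ------

// [[Rcpp::export]]
arma::mat add_bias_cpp(arma::mat X, const arma::rowvec& v) {
  X.each_row() += v;
  return X;
}

// [[Rcpp::export]]
arma::mat relu_cpp(arma::mat X) {
  X.elem(find(X < 0)).zeros();
  return X;
}

// layer norm over rows: y = g * (x - mean) / sqrt(var + eps) + b
// [[Rcpp::export]]
Rcpp::List ln_forward_cpp(const arma::mat& X, const arma::rowvec& g,
                          const arma::rowvec& b, double eps) {
  arma::vec mu = mean(X, 1);
  arma::mat xc = X.each_col() - mu;
  arma::vec si = 1.0 / sqrt(mean(square(xc), 1) + eps);
  arma::mat xhat = xc.each_col() % si;
  arma::mat y = xhat.each_row() % g;
  y.each_row() += b;
  return Rcpp::List::create(Rcpp::Named("y") = y,
                            Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("si") = si);
}

// [[Rcpp::export]]
Rcpp::List ln_backward_cpp(const arma::mat& dy, const arma::mat& xhat,
                           const arma::vec& si, const arma::rowvec& g) {
  arma::mat dxhat = dy.each_row() % g;
  arma::vec m1 = mean(dxhat, 1);
  arma::vec m2 = mean(dxhat % xhat, 1);
  arma::mat dx = dxhat.each_col() - m1;
  dx -= xhat.each_col() % m2;
  dx.each_col() %= si;
  return Rcpp::List::create(
    Rcpp::Named("dx") = dx,
    Rcpp::Named("dg") = sum(dy % xhat, 0),
    Rcpp::Named("db") = sum(dy, 0));
}
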