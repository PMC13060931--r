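#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Exact Kalman filter + RTS smoother for one trial of a time-invariant
// linear-Gaussian state-space model:
//   x_{t+1} = A x_t + b + N(0, Q),  x_1 ~ N(mu1, S1),  y_t = C x_t + N(0, R).
//
// Covariance measurement updates use the Joseph form; the marginal
// log-likelihood is accumulated from the innovation decomposition.
//
// Returns smoothed means (T x D), smoothed covariances (D x D x T),
// lag-one smoothed cross-covariances Cov(x_t, x_{t+1}) (D x D x (T-1)),
// and the exact marginal log-likelihood of the trial.

// [[Rcpp::export]]
Rcpp::List kalman_smooth_cpp(const arma::mat& y, const arma::mat& A,
                             const arma::vec& b, const arma::mat& Q,
                             const arma::mat& C, const arma::mat& R,
                             const arma::vec& mu1, const arma::mat& S1,
                             const bool want_smooth = true) {
  const uword T = y.n_rows;
  const uword D = A.n_rows;
  const uword N = C.n_rows;

  mat mf(D, T), mp(D, T);       // filtered / predicted means
  cube Pf(D, D, T), Pp(D, D, T);
  double ll = 0.0;
  const mat ID = eye<mat>(D, D);
  const double log2pi = std::log(2.0 * datum::pi);

  vec m = mu1;
  mat P = S1;
  for (uword t = 0; t < T; ++t) {
    if (t > 0) {
      m = A * m + b;
      P = A * P * A.t() + Q;
      P = 0.5 * (P + P.t());
    }
    mp.col(t) = m;
    Pp.slice(t) = P;

    // measurement update
    vec yt = y.row(t).t();
    vec innov = yt - C * m;
    mat S = C * P * C.t() + R;
    S = 0.5 * (S + S.t());
    mat L;
    if (!chol(L, S, "lower")) {
      Rcpp::stop("innovation covariance not positive definite at timestep %d",
                 (int)(t + 1));
    }
    // log N(y_t; C m, S)
    vec alpha = solve(trimatl(L), innov);
    ll += -0.5 * (N * log2pi) - accu(log(L.diag())) - 0.5 * dot(alpha, alpha);

    mat K = P * C.t();                 // D x N, then solve against S
    K = solve(S, K.t()).t();           // K = P C' S^{-1}
    m = m + K * innov;
    mat IKC = ID - K * C;
    P = IKC * P * IKC.t() + K * R * K.t();   // Joseph form
    P = 0.5 * (P + P.t());
    mf.col(t) = m;
    Pf.slice(t) = P;
  }

  if (!want_smooth) {
    return Rcpp::List::create(Rcpp::Named("loglik") = ll);
  }

  // RTS backward pass
  mat ms(D, T);
  cube Ps(D, D, T);
  cube cross(D, D, T > 1 ? T - 1 : 0);   // Cov(x_t, x_{t+1})
  ms.col(T - 1) = mf.col(T - 1);
  Ps.slice(T - 1) = Pf.slice(T - 1);
  for (uword t = T - 1; t-- > 0;) {
    // G = Pf_t A' Pp_{t+1}^{-1}
    mat G = solve(Pp.slice(t + 1), A * Pf.slice(t)).t();
    ms.col(t) = mf.col(t) + G * (ms.col(t + 1) - mp.col(t + 1));
    mat Pst = Pf.slice(t) + G * (Ps.slice(t + 1) - Pp.slice(t + 1)) * G.t();
    Ps.slice(t) = 0.5 * (Pst + Pst.t());
    cross.slice(t) = G * Ps.slice(t + 1);
  }

  return Rcpp::List::create(
      Rcpp::Named("mean") = ms.t(),
      Rcpp::Named("var") = Ps,
      Rcpp::Named("cross") = cross,
      Rcpp::Named("loglik") = ll);
}
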