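// Full-covariance Gaussian-mixture EM inner loop. One call runs a single
// initialization to convergence; restart selection stays in R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// n x K matrix of log(w_k) + log N(x_i | mu_k, Sigma_k)
static mat logDensity(const mat& S, const rowvec& w, const mat& mu,
                      const cube& Sig) {
  const uword n = S.n_rows, m = S.n_cols, K = w.n_elem;
  mat L(n, K);
  const double cst = m * std::log(2.0 * M_PI);
  for (uword k = 0; k < K; ++k) {
    mat C;
    if (!chol(C, Sig.slice(k)))
      Rcpp::stop("covariance not positive-definite in EM");
    double logdet = 2.0 * accu(log(C.diag()));
    mat Xc = S.each_row() - mu.row(k);
    // Mahalanobis via C' V = Xc'
    mat V = solve(trimatl(C.t()), Xc.t());
    rowvec z = sum(V % V, 0);
    L.col(k) = std::log(w(k)) - 0.5 * (cst + logdet + z.t());
  }
  return L;
}

// [[Rcpp::export(name = ".cpp_run_em")]]
Rcpp::List cpp_run_em(const arma::mat& S, const arma::mat& mu0,
                      int maxIter, double tol, double covFloor) {
  const uword n = S.n_rows, m = S.n_cols, K = mu0.n_rows;
  rowvec w(K, fill::value(1.0 / K));
  mat mu = mu0;
  rowvec v0 = var(S, 0, 0);
  v0.transform([&](double v) {
    return std::max(std::isfinite(v) ? v : 0.0, covFloor); });
  cube Sig(m, m, K);
  for (uword k = 0; k < K; ++k) Sig.slice(k) = diagmat(v0);

  std::vector<double> trace;
  double llPrev = -datum::inf;
  bool converged = false;
  for (int it = 0; it < maxIter; ++it) {
    mat L = logDensity(S, w, mu, Sig);
    vec mx = max(L, 1);
    vec rowLL = mx + log(sum(exp(L.each_col() - mx), 1));
    double ll = accu(rowLL);
    trace.push_back(ll);
    if (it > 0 && ll - llPrev < tol) { converged = true; break; }
    llPrev = ll;
    mat R = exp(L.each_col() - rowLL);
    rowvec Nk = clamp(sum(R, 0), 1e-300, datum::inf);
    w = Nk / n;
    mat RtS = R.t() * S;
    mu = RtS.each_col() / Nk.t();
    for (uword k = 0; k < K; ++k) {
      mat Xc = S.each_row() - mu.row(k);
      Sig.slice(k) = (Xc.each_col() % R.col(k)).t() * Xc / Nk(k);
      // floor only near-singular covariances: the exact M-step update is
      // what makes EM monotone, so the ridge is applied only when an
      // eigenvalue would drop below the floor
      vec ev = eig_sym(Sig.slice(k));
      if (ev.min() < covFloor) Sig.slice(k).diag() += covFloor;
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("weights") = Rcpp::NumericVector(w.begin(), w.end()),
    Rcpp::Named("means") = mu,
    Rcpp::Named("covariances") = Sig,
    Rcpp::Named("logLik") = trace.back(),
    Rcpp::Named("trace") = trace,
    Rcpp::Named("converged") = converged);
}
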