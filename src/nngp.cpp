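#include <RcppArmadillo.h>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Vecchia / NNGP Gaussian log-likelihood machinery, exponential kernel.
//
// Inputs are pre-ordered (conditioning order) and the neighbor geometry is
// precomputed once per dataset:
//   nn      : n x m neighbor index matrix (0-based positions in the ordered
//             data; -1 padding where a point has fewer than m predecessors)
//   d_self  : n x m distances from each point to its neighbors (0 padding)
//   d_pair  : n x (m*m) distances among the neighbors of each point,
//             row-major flattening of the m x m matrix (0 padding)
//
// For each ordered point k with q = n_nb[k] neighbors N(k):
//   Cnn = sigma2 * exp(-Dnn / l) + tau2 * I   (q x q)
//   c   = sigma2 * exp(-d / l)                (q)
//   b   = Cnn^{-1} c,  F_k = sigma2 + tau2 - c'b
// The joint density factorises into univariate conditionals; with
// u_k = (y_k - b'y_N)/sqrt(F_k) and rows V_k = (x_k - b'X_N)/sqrt(F_k),
// beta is profiled by OLS of u on V and
//   loglik = -0.5 * ( n log(2*pi) + sum(log F_k) + RSS ).

// Computes the whitened residual sum of squares, log-determinant and the
// profiled GLS beta. Returns false on a rank-deficient design.
static bool vecchia_profile(const vec& y, const mat& X,
                            const imat& nn, const ivec& n_nb,
                            const mat& d_self, const mat& d_pair,
                            const double sigma2, const double tau2,
                            const double lengthscale,
                            double& logdet, double& rss, vec& beta) {
  const uword n = y.n_elem;
  const uword p = X.n_cols;
  const uword m = nn.n_cols;
  const double marg = sigma2 + tau2;
  const double inv_l = 1.0 / lengthscale;

  std::vector<double> C(m * m), cvec(m), b(m);
  mat VtV(p, p, fill::zeros);
  vec Vtu(p, fill::zeros);
  rowvec vrow(p);
  logdet = 0.0;
  rss = 0.0;

  for (uword k = 0; k < n; ++k) {
    const int q = n_nb(k);
    double f, resid;
    if (q == 0) {
      f = marg;
      logdet += std::log(f);
      const double s = 1.0 / std::sqrt(f);
      resid = y(k) * s;
      vrow = X.row(k) * s;
    } else {
      // lower triangle of the neighbor covariance + rhs
      for (int a = 0; a < q; ++a) {
        cvec[a] = sigma2 * std::exp(-d_self(k, a) * inv_l);
        double* Ca = &C[a * q];
        for (int j = 0; j < a; ++j)
          Ca[j] = sigma2 * std::exp(-d_pair.at(k, a * m + j) * inv_l);
        Ca[a] = marg;
      }
      // in-place Cholesky (row-major lower triangle)
      for (int a = 0; a < q; ++a) {
        double* Ca = &C[a * q];
        for (int j = 0; j < a; ++j) {
          double s = Ca[j];
          const double* Cj = &C[j * q];
          for (int t = 0; t < j; ++t) s -= Ca[t] * Cj[t];
          Ca[j] = s / Cj[j];
        }
        double s = Ca[a];
        for (int t = 0; t < a; ++t) s -= Ca[t] * Ca[t];
        if (s <= 0.0) s = 1e-12 * marg;
        Ca[a] = std::sqrt(s);
      }
      // solve L L' b = c
      for (int a = 0; a < q; ++a) {
        double s = cvec[a];
        const double* Ca = &C[a * q];
        for (int t = 0; t < a; ++t) s -= Ca[t] * b[t];
        b[a] = s / Ca[a];
      }
      double cb = 0.0;
      for (int a = 0; a < q; ++a) cb += b[a] * b[a];  // c' Cnn^-1 c
      for (int a = q - 1; a >= 0; --a) {
        double s = b[a];
        for (int t = a + 1; t < q; ++t) s -= C[t * q + a] * b[t];
        b[a] = s / C[a * q + a];
      }
      f = marg - cb;
      if (f < 1e-12 * marg) f = 1e-12 * marg;
      logdet += std::log(f);
      const double s = 1.0 / std::sqrt(f);
      double ynb = 0.0;
      vrow = X.row(k);
      for (int a = 0; a < q; ++a) {
        const uword j = static_cast<uword>(nn(k, a));
        ynb += b[a] * y(j);
        vrow -= b[a] * X.row(j);
      }
      resid = (y(k) - ynb) * s;
      vrow *= s;
    }
    // accumulate the normal equations of the whitened regression
    for (uword a = 0; a < p; ++a) {
      Vtu(a) += vrow(a) * resid;
      for (uword bb = 0; bb <= a; ++bb) VtV(a, bb) += vrow(a) * vrow(bb);
    }
    rss += resid * resid;  // y-part; corrected below by beta' Vtu
  }
  VtV = symmatl(VtV);
  bool ok = solve(beta, VtV, Vtu,
                  solve_opts::likely_sympd + solve_opts::no_approx);
  if (!ok) return false;
  // RSS of u - V beta = u'u - beta' V'u (normal equations)
  rss -= dot(beta, Vtu);
  if (rss < 0.0) rss = 0.0;
  return true;
}

// [[Rcpp::export]]
Rcpp::List nngp_loglik_cpp(const arma::vec& y,
                           const arma::mat& X,
                           const arma::imat& nn,
                           const arma::ivec& n_nb,
                           const arma::mat& d_self,
                           const arma::mat& d_pair,
                           const double sigma2,
                           const double tau2,
                           const double lengthscale) {
  double logdet, rss;
  vec beta;
  if (!vecchia_profile(y, X, nn, n_nb, d_self, d_pair,
                       sigma2, tau2, lengthscale, logdet, rss, beta))
    Rcpp::stop("rank-deficient design after whitening");
  const double n = static_cast<double>(y.n_elem);
  const double ll = -0.5 * (n * std::log(2.0 * M_PI) + logdet + rss);
  return Rcpp::List::create(Rcpp::Named("loglik") = ll,
                            Rcpp::Named("beta") = beta,
                            Rcpp::Named("rss") = rss,
                            Rcpp::Named("logdet") = logdet);
}

// Likelihood only (hot path for the optimizer).
// [[Rcpp::export]]
double nngp_loglik_value_cpp(const arma::vec& y,
                             const arma::mat& X,
                             const arma::imat& nn,
                             const arma::ivec& n_nb,
                             const arma::mat& d_self,
                             const arma::mat& d_pair,
                             const double sigma2,
                             const double tau2,
                             const double lengthscale) {
  double logdet, rss;
  vec beta;
  if (!vecchia_profile(y, X, nn, n_nb, d_self, d_pair,
                       sigma2, tau2, lengthscale, logdet, rss, beta))
    return -std::numeric_limits<double>::infinity();
  const double n = static_cast<double>(y.n_elem);
  return -0.5 * (n * std::log(2.0 * M_PI) + logdet + rss);
}

// Profiled likelihood over the total variance: with
// Sigma = v * (s K + (1 - s) I), the Vecchia factors at unit variance give
// vhat = RSS / n in closed form and
//   max_v loglik = -0.5 * ( n log(2 pi) + n log(vhat) + logdet + n ).
// Returns (profiled loglik, vhat). Used by the 2-D (s, l) optimizer.
// [[Rcpp::export]]
Rcpp::NumericVector nngp_profiled_value_cpp(const arma::vec& y,
                                            const arma::mat& X,
                                            const arma::imat& nn,
                                            const arma::ivec& n_nb,
                                            const arma::mat& d_self,
                                            const arma::mat& d_pair,
                                            const double prop_spatial,
                                            const double lengthscale) {
  double logdet, rss;
  vec beta;
  if (!vecchia_profile(y, X, nn, n_nb, d_self, d_pair,
                       prop_spatial, 1.0 - prop_spatial, lengthscale,
                       logdet, rss, beta)) {
    return Rcpp::NumericVector::create(
        -std::numeric_limits<double>::infinity(), 1.0);
  }
  const double n = static_cast<double>(y.n_elem);
  double vhat = rss / n;
  if (vhat < 1e-300) vhat = 1e-300;
  const double ll =
      -0.5 * (n * std::log(2.0 * M_PI) + n * std::log(vhat) + logdet + n);
  return Rcpp::NumericVector::create(ll, vhat);
}
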