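#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Rational-quadratic ARD covariance between the rows of X1 and X2:
//   k(x, x') = sf2 * (1 + r2/(2*alpha))^(-alpha),
//   r2 = sum_d ((x_d - x'_d)/ell_d)^2.
// Squared distances are accumulated per dimension (no |x|^2 - 2xy trick) so
// the result agrees with a naive double-loop oracle to machine precision.
static arma::mat ard_sqdist(const arma::mat& X1, const arma::mat& X2,
                            const arma::vec& ell) {
  const arma::uword n1 = X1.n_rows, n2 = X2.n_rows, d = X1.n_cols;
  arma::mat S(n1, n2, arma::fill::zeros);
  for (arma::uword k = 0; k < d; ++k) {
    const double inv_ell = 1.0 / ell(k);
    const arma::vec a = X1.col(k) * inv_ell;
    const arma::vec b = X2.col(k) * inv_ell;
    for (arma::uword j = 0; j < n2; ++j) {
      const double bj = b(j);
      for (arma::uword i = 0; i < n1; ++i) {
        const double diff = a(i) - bj;
        S(i, j) += diff * diff;
      }
    }
  }
  return S;
}

// [[Rcpp::export(name = "rq_kernel_cpp")]]
arma::mat rq_kernel_cpp(const arma::mat& X1, const arma::mat& X2,
                        double sf2, double alpha, const arma::vec& ell) {
  arma::mat S = ard_sqdist(X1, X2, ell);
  return sf2 * arma::pow(1.0 + S / (2.0 * alpha), -alpha);
}

// Negative log marginal likelihood of a GP with RQ-ARD covariance plus
// Gaussian observation noise, and its gradient with respect to the
// log-hyperparameters theta = (log sf2, log sn2, log alpha, log ell_1..d).
//
// nlml = 0.5 y' Ky^-1 y + 0.5 log|Ky| + (n/2) log(2 pi),  Ky = K + sn2 I.
// d nlml / d theta_j = 0.5 tr( (Ky^-1 - a a') dKy/dtheta_j ),  a = Ky^-1 y.
//
// If the Cholesky fails, a diagonal jitter ladder up to jitter_max (relative
// to sf2 + sn2) is climbed; `ok = false` is returned when even that fails.
// [[Rcpp::export(name = "gp_nlml_cpp")]]
List gp_nlml_cpp(const arma::vec& theta, const arma::mat& X,
                 const arma::vec& y, bool want_grad = true,
                 double jitter_max = 1e-4) {
  const arma::uword n = X.n_rows, d = X.n_cols;
  if (theta.n_elem != d + 3)
    stop("theta must have length ncol(X) + 3");
  const double sf2 = std::exp(theta(0));
  const double sn2 = std::exp(theta(1));
  const double alpha = std::exp(theta(2));
  const arma::vec ell = arma::exp(theta.subvec(3, d + 2));

  arma::mat S = ard_sqdist(X, X, ell);
  arma::mat B = 1.0 + S / (2.0 * alpha);
  arma::mat logB = arma::log(B);
  arma::mat Kq = sf2 * arma::exp(-alpha * logB);   // = sf2 * B^(-alpha)
  arma::mat Ky = Kq;
  Ky.diag() += sn2;

  if (!Ky.is_finite())
    return List::create(_["value"] = R_PosInf, _["ok"] = false,
                        _["jitter"] = NA_REAL);

  arma::mat L;
  double jitter = 0.0;
  bool ok = arma::chol(L, Ky, "lower");
  if (!ok) {
    const double scale = sf2 + sn2;
    for (double j = 1e-10; j <= jitter_max * 1.0000001; j *= 10.0) {
      arma::mat Kj = Ky;
      Kj.diag() += j * scale;
      if (arma::chol(L, Kj, "lower")) { ok = true; jitter = j * scale; break; }
    }
  }
  if (!ok)
    return List::create(_["value"] = R_PosInf, _["ok"] = false,
                        _["jitter"] = NA_REAL);

  arma::vec a = arma::solve(arma::trimatl(L), y);
  const double quad = arma::dot(a, a);           // y' Ky^-1 y
  a = arma::solve(arma::trimatu(L.t()), a);      // alpha = Ky^-1 y
  const double nlml = 0.5 * quad + arma::accu(arma::log(L.diag())) +
    0.5 * n * std::log(2.0 * M_PI);

  if (!want_grad)
    return List::create(_["value"] = nlml, _["ok"] = true,
                        _["jitter"] = jitter);

  arma::mat Li = arma::inv(arma::trimatl(L));
  arma::mat W = Li.t() * Li;                     // Ky^-1
  W -= a * a.t();

  arma::vec g(d + 3);
  g(0) = 0.5 * arma::accu(W % Kq);               // d/d log sf2
  g(1) = 0.5 * sn2 * arma::trace(W);             // d/d log sn2
  // d k / d log alpha = k * (-alpha log B + S / (2B))
  g(2) = 0.5 * arma::accu(W % (Kq % (-alpha * logB + S / (2.0 * B))));
  // d k / d log ell_k = sf2 * B^(-alpha-1) * ((x_k - x'_k)/ell_k)^2
  arma::mat WC = W % (Kq / B);                   // sf2 * B^(-alpha-1)
  for (arma::uword k = 0; k < d; ++k) {
    const arma::vec xk = X.col(k) / ell(k);
    double acc = 0.0;
    for (arma::uword j = 0; j < n; ++j) {
      const double xj = xk(j);
      for (arma::uword i = 0; i < n; ++i) {
        const double diff = xk(i) - xj;
        acc += WC(i, j) * diff * diff;
      }
    }
    g(3 + k) = 0.5 * acc;
  }

  return List::create(_["value"] = nlml, _["grad"] = g, _["ok"] = true,
                      _["jitter"] = jitter);
}
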