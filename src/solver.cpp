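// Inner loops of the L1-penalized multivariate regression with joint
// sparse precision estimation: cyclic coordinate descent for the
// coefficient step and a Friedman-style block coordinate graphical
// lasso for the precision step.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double softThresh(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// One coefficient step: minimize over B (given Theta)
//   (1/n) tr[(Y - ZB)' (Y - ZB) Theta] + lambda * sum_{j in pen} |B_jk|
// by cyclic coordinate descent with an active-set strategy: after a full
// pass, iterate only over rows with nonzero (or unpenalized) entries
// until stable, then confirm with another full pass. B and R (= Y - ZB)
// are updated in place and returned.
static double sweepRows(const arma::mat& Z, arma::mat& B, arma::mat& R,
                        const arma::mat& Theta, const arma::vec& zss,
                        const arma::uvec& penalized, double lambda,
                        double n, const std::vector<int>& rows) {
  const int q = B.n_cols;
  double maxDelta = 0.0;
  for (int j : rows) {
    if (zss(j) < 1e-300) continue;
    rowvec zjR = Z.col(j).t() * R;           // 1 x q
    rowvec u = (2.0 / n) * (zjR * Theta);    // gradient pieces
    for (int k = 0; k < q; ++k) {
      double a = (2.0 / n) * zss(j) * Theta(k, k);
      if (a < 1e-300) continue;
      double bOld = B(j, k);
      double cand = bOld + u(k) / a;
      double bNew = penalized(j) ? softThresh(cand, lambda / a) : cand;
      double delta = bNew - bOld;
      if (delta != 0.0) {
        B(j, k) = bNew;
        R.col(k) -= delta * Z.col(j);
        // keep the cached gradient row consistent with updated R
        u -= (2.0 / n) * delta * zss(j) * Theta.row(k);
        double scale = std::max(1.0, std::abs(bNew));
        maxDelta = std::max(maxDelta, std::abs(delta) / scale);
      }
    }
  }
  return maxDelta;
}

// [[Rcpp::export]]
Rcpp::List cppGammaStep(const arma::mat& Z, const arma::mat& Y,
                        arma::mat B, const arma::mat& Theta,
                        const arma::uvec& penalized, double lambda,
                        double tol, int maxSweeps) {
  const int n = Z.n_rows, p = Z.n_cols;
  (void)n;
  vec zss(p);
  for (int j = 0; j < p; ++j) zss(j) = dot(Z.col(j), Z.col(j));
  mat R = Y - Z * B;
  std::vector<int> all(p);
  for (int j = 0; j < p; ++j) all[j] = j;
  int sweeps = 0;
  while (sweeps < maxSweeps) {
    double d = sweepRows(Z, B, R, Theta, zss, penalized, lambda,
                         (double)Z.n_rows, all);
    ++sweeps;
    if (d < tol) break;
    // active rows: unpenalized or currently nonzero
    std::vector<int> act;
    for (int j = 0; j < p; ++j)
      if (!penalized(j) || arma::any(B.row(j) != 0.0)) act.push_back(j);
    while (sweeps < maxSweeps) {
      double da = sweepRows(Z, B, R, Theta, zss, penalized, lambda,
                            (double)Z.n_rows, act);
      ++sweeps;
      if (da < tol) break;
    }
  }
  return Rcpp::List::create(Rcpp::Named("B") = B, Rcpp::Named("R") = R,
                            Rcpp::Named("sweeps") = sweeps);
}

// Graphical lasso: minimize tr(S Theta) - logdet(Theta) + rho ||Theta||_{1,off}
// over positive-definite Theta (diagonal unpenalized), by block coordinate
// descent on the covariance W (Friedman et al.), inner lasso by coordinate
// descent.
// [[Rcpp::export]]
Rcpp::List cppGlasso(const arma::mat& S, double rho, double tol, int maxIter) {
  const int q = S.n_rows;
  mat W = S;                       // working covariance, diagonal unpenalized
  mat Bmat(q - 1, q, fill::zeros); // inner lasso coefficients per column
  double dW = datum::inf;
  int it = 0;
  for (it = 1; it <= maxIter && dW > tol; ++it) {
    dW = 0.0;
    for (int j = 0; j < q; ++j) {
      uvec idx(q - 1);
      int c = 0;
      for (int t = 0; t < q; ++t) if (t != j) idx(c++) = t;
      mat W11 = W.submat(idx, idx);
      vec s12 = S.col(j); s12 = s12.elem(idx);
      vec beta = Bmat.col(j);
      // lasso: min 0.5 b' W11 b - s12' b + rho |b|_1
      for (int inner = 0; inner < 500; ++inner) {
        double mx = 0.0;
        for (int a = 0; a < q - 1; ++a) {
          double grad = s12(a) - dot(W11.row(a), beta) + W11(a, a) * beta(a);
          double bNew = softThresh(grad, rho) / W11(a, a);
          double d = std::abs(bNew - beta(a));
          beta(a) = bNew;
          mx = std::max(mx, d);
        }
        if (mx < tol * 0.1) break;
      }
      Bmat.col(j) = beta;
      vec w12 = W11 * beta;
      for (int a = 0; a < q - 1; ++a) {
        dW = std::max(dW, std::abs(W(idx(a), j) - w12(a)));
        W(idx(a), j) = w12(a);
        W(j, idx(a)) = w12(a);
      }
    }
  }
  // recover Theta from W and the lasso coefficients
  mat Theta(q, q, fill::zeros);
  for (int j = 0; j < q; ++j) {
    uvec idx(q - 1);
    int c = 0;
    for (int t = 0; t < q; ++t) if (t != j) idx(c++) = t;
    vec beta = Bmat.col(j);
    vec w12 = W.col(j); w12 = w12.elem(idx);
    double t22 = 1.0 / (W(j, j) - dot(w12, beta));
    Theta(j, j) = t22;
    for (int a = 0; a < q - 1; ++a) Theta(idx(a), j) = -beta(a) * t22;
  }
  Theta = 0.5 * (Theta + Theta.t());
  return Rcpp::List::create(Rcpp::Named("Theta") = Theta,
                            Rcpp::Named("W") = W,
                            Rcpp::Named("iterations") = it);
}
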