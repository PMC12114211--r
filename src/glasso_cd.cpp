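#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// Blockwise coordinate descent for the off-diagonal-penalised Gaussian
// log-likelihood:  maximise  log det(Theta) - tr(S Theta) - lambda * sum_{i!=j} |Theta_ij|.
// Works on the covariance estimate W (= Theta^{-1} at convergence); each column
// update is a lasso regression solved by coordinate descent.  Stopping uses the
// duality gap  tr(S Theta) + lambda * ||Theta||_{1,off} - p, which is >= 0 once
// W is dual feasible (guaranteed columnwise by the lasso KKT conditions).
// [[Rcpp::export]]
Rcpp::List glasso_cd(const arma::mat& S, double lambda,
                     double tol, int max_sweeps,
                     Rcpp::Nullable<Rcpp::NumericMatrix> W_init = R_NilValue,
                     Rcpp::Nullable<Rcpp::NumericMatrix> B_init = R_NilValue) {
  const int p = S.n_rows;
  mat W;
  if (W_init.isNotNull()) {
    W = Rcpp::as<mat>(W_init.get());
    W.diag() = S.diag();  // diagonal is unpenalised: W_ii = S_ii always
  } else {
    W = S;
  }
  // B(k, j): lasso coefficient of variable k in the regression for column j
  mat B = B_init.isNotNull() ? Rcpp::as<mat>(B_init.get()) : mat(p, p, fill::zeros);

  const double inner_tol = 1e-10;
  const int inner_max = 1000;

  mat Theta(p, p, fill::zeros);
  double gap = datum::inf;
  bool converged = false;
  int sweep = 0;

  for (sweep = 1; sweep <= max_sweeps; ++sweep) {
    for (int j = 0; j < p; ++j) {
      // index vector of the other p-1 variables
      uvec idx(p - 1);
      int c = 0;
      for (int k = 0; k < p; ++k) if (k != j) idx(c++) = k;

      mat V = W.submat(idx, idx);           // W11
      vec s12 = S.col(j);
      vec s = s12.elem(idx);
      vec beta = B.col(j);
      vec b = beta.elem(idx);
      vec u = V * b;                        // running V %*% b

      for (int it = 0; it < inner_max; ++it) {
        double del_max = 0.0;
        for (int k = 0; k < p - 1; ++k) {
          double bk = b(k);
          double r = s(k) - (u(k) - V(k, k) * bk);
          double bnew = soft(r, lambda) / V(k, k);
          double d = bnew - bk;
          if (d != 0.0) {
            b(k) = bnew;
            u += d * V.col(k);
            double ad = std::fabs(d);
            if (ad > del_max) del_max = ad;
          }
        }
        if (del_max < inner_tol) break;
      }

      vec w12 = V * b;
      for (int k = 0; k < p - 1; ++k) {
        W(idx(k), j) = w12(k);
        W(j, idx(k)) = w12(k);
      }
      vec bfull(p, fill::zeros);
      bfull.elem(idx) = b;
      B.col(j) = bfull;
    }

    // recover the sparse Theta from the regression coefficients
    for (int j = 0; j < p; ++j) {
      double dotwb = 0.0;
      for (int k = 0; k < p; ++k) if (k != j) dotwb += W(k, j) * B(k, j);
      double tjj = 1.0 / (W(j, j) - dotwb);
      Theta(j, j) = tjj;
      for (int k = 0; k < p; ++k) if (k != j) Theta(k, j) = -B(k, j) * tjj;
    }
    Theta = 0.5 * (Theta + Theta.t());

    // duality-gap certificate: project W onto the dual-feasible box
    // |Wd - S|_off <= lambda; then f* <= -logdet(Wd) - p bounds the
    // suboptimality of the recovered Theta from above.
    mat Wd = W;
    for (int i = 0; i < p; ++i)
      for (int j = 0; j < p; ++j) if (i != j) {
        double d = W(i, j) - S(i, j);
        if (d > lambda) d = lambda;
        if (d < -lambda) d = -lambda;
        Wd(i, j) = S(i, j) + d;
      }
    Wd = 0.5 * (Wd + Wd.t());
    double ld_wd, ld_th, sign;
    bool ok1 = log_det(ld_wd, sign, Wd) && sign > 0;
    bool ok2 = log_det(ld_th, sign, Theta) && sign > 0;
    if (ok1 && ok2) {
      double l1off = 0.0, trst = 0.0;
      for (int i = 0; i < p; ++i)
        for (int j = 0; j < p; ++j) {
          trst += S(i, j) * Theta(i, j);
          if (i != j) l1off += std::fabs(Theta(i, j));
        }
      double f_theta = ld_th - trst - lambda * l1off;
      gap = (-ld_wd - (double)p) - f_theta;
      if (gap < tol) { converged = true; break; }
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("theta") = Theta,
    Rcpp::Named("w") = W,
    Rcpp::Named("beta") = B,
    Rcpp::Named("gap") = gap,
    Rcpp::Named("sweeps") = std::min(sweep, max_sweeps),
    Rcpp::Named("converged") = converged);
}
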