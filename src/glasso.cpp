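#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// E(A) = -log det A + tr(SA) + lam * sum_ij |a_ij|
static double penalized_objective_cpp(const mat& A, const mat& S, double lam) {
  double ld, sign;
  log_det(ld, sign, A);
  if (sign <= 0) return datum::inf;
  return -ld + accu(S % A) + lam * accu(abs(A));
}

// [[Rcpp::export(name = ".glasso_core")]]
Rcpp::List glasso_core(const arma::mat& S, double lam,
                       Rcpp::Nullable<Rcpp::NumericMatrix> A_init,
                       double tol, int max_sweeps, double inner_tol) {
  const uword m = S.n_rows;
  mat A, W;
  if (A_init.isNotNull()) {
    A = Rcpp::as<mat>(A_init.get());
    A = 0.5 * (A + A.t());
    W = inv_sympd(A);
  } else {
    W = S + lam * eye(m, m);
    A = inv_sympd(W);
  }

  std::vector<double> trace;
  trace.push_back(penalized_objective_cpp(A, S, lam));

  bool converged = false;
  int sweeps_done = 0;
  vec alpha(m), q(m), w12(m), s_col(m);

  for (int sweep = 1; sweep <= max_sweeps; ++sweep) {
    mat A_old = A;
    for (uword j = 0; j < m; ++j) {
      const double d22 = S(j, j) + lam;  // = 1/c at the column optimum
      const double w22 = W(j, j);
      w12 = W.col(j);  w12(j) = 0.0;
      alpha = A.col(j); alpha(j) = 0.0;  // warm start from current column
      s_col = S.col(j);

      // Inner problem (printed subgradient equations for a12 with A11 fixed):
      //   min_a  0.5 d22 * a' H a + s12' a + lam ||a||_1,
      // with H = A11^{-1} = W11 - w12 w12'/w22.  Coordinate descent with
      // q = W * alpha maintained incrementally (entry j of q is unused).
      q = W * alpha;
      double r = dot(w12, alpha);
      for (int pass = 0; pass < 1000; ++pass) {
        double maxdiff = 0.0;
        for (uword k = 0; k < m; ++k) {
          if (k == j) continue;
          const double hkk = W(k, k) - w12(k) * w12(k) / w22;
          double dk = d22 * hkk;
          if (dk < 1e-12) dk = 1e-12;
          const double halpha_k = q(k) - w12(k) * r / w22;
          const double z = -(d22 * (halpha_k - hkk * alpha(k)) + s_col(k));
          double anew = 0.0;
          if (z > lam)       anew = (z - lam) / dk;
          else if (z < -lam) anew = (z + lam) / dk;
          const double delta = anew - alpha(k);
          if (delta != 0.0) {
            alpha(k) = anew;
            q += delta * W.col(k);
            r += delta * w12(k);
            const double ad = std::abs(delta);
            if (ad > maxdiff) maxdiff = ad;
          }
        }
        if (maxdiff < inner_tol) break;
      }

      // Recover the diagonal entry from the a22 stationarity condition:
      // a22 - a12' A11^{-1} a12 = 1/(s22 + lam).
      vec u = q - (r / w22) * w12;  // u = H alpha
      u(j) = 0.0;
      const double quad = dot(alpha, u);
      const double a22 = 1.0 / d22 + quad;

      A.col(j) = alpha; A.row(j) = alpha.t(); A(j, j) = a22;

      // Keep W = A^{-1} exactly: with H in the (idx,idx) block,
      //   W11_new = H + d22 * u u',  w12_new = -d22 * u,  w22_new = d22.
      vec w12f = W.col(j);  // includes w22 at position j
      W -= w12f * w12f.t() / w22;  // (idx,idx) -> H, row/col j -> 0
      W += d22 * (u * u.t());      // u(j) = 0, row/col j untouched
      vec w12new = -d22 * u;
      W.col(j) = w12new; W.row(j) = w12new.t(); W(j, j) = d22;
    }
    sweeps_done = sweep;
    trace.push_back(penalized_objective_cpp(A, S, lam));
    const double mac = accu(abs(A - A_old)) / double(m * m);
    // refresh the inverse once per sweep to stop rank-one drift
    W = inv_sympd(A);
    if (mac < tol) { converged = true; break; }
  }

  return Rcpp::List::create(
    Rcpp::Named("A") = A,
    Rcpp::Named("objective_trace") = trace,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("sweeps") = sweeps_done);
}

// Pairwise chi-square distance between columns of x, with the
// (x_+1 + x_+2)/(x_i1 + x_i2) weight; positions with x_i1 + x_i2 = 0
// contribute nothing (their numerator is also zero).
// [[Rcpp::export(name = ".chi2_distance_matrix")]]
arma::mat chi2_distance_matrix(const arma::mat& x) {
  const uword n = x.n_rows, m = x.n_cols;
  rowvec cs = sum(x, 0);
  mat D(m, m, fill::zeros);
  for (uword a = 0; a < m; ++a) {
    for (uword b = a + 1; b < m; ++b) {
      double acc = 0.0;
      const double tot = cs(a) + cs(b);
      for (uword i = 0; i < n; ++i) {
        const double denom = x(i, a) + x(i, b);
        if (denom > 0) {
          const double d = std::sqrt(x(i, a) / cs(a)) - std::sqrt(x(i, b) / cs(b));
          acc += tot / denom * d * d;
        }
      }
      D(a, b) = D(b, a) = std::sqrt(acc);
    }
  }
  return D;
}
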