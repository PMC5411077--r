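#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Lawson-Hanson active-set NNLS on the normal equations for one right-hand
// side: minimise ||b - A x||^2 s.t. x >= 0, given G = A'A and g = A'b.
// Rank-deficient passive systems fall back to the least-norm (pinv) solution.
static vec nnls_one(const mat& G, const vec& g, const double tol) {
  const uword r = G.n_rows;
  vec x(r, fill::zeros);
  std::vector<bool> passive(r, false);
  vec w = g;  // negative gradient g - G x at x = 0

  const uword max_outer = 30 * r + 30;
  uword outer = 0;

  while (outer++ < max_outer) {
    // most violating variable on the zero set
    double wmax = -datum::inf;
    sword t = -1;
    for (uword j = 0; j < r; ++j) {
      if (!passive[j] && w(j) > wmax) {
        wmax = w(j);
        t = static_cast<sword>(j);
      }
    }
    if (t < 0 || wmax <= tol) break;
    passive[static_cast<uword>(t)] = true;

    uword inner = 0;
    const uword max_inner = 30 * r + 30;
    while (inner++ < max_inner) {
      uvec P(r);
      uword np = 0;
      for (uword j = 0; j < r; ++j)
        if (passive[j]) P(np++) = j;
      P.resize(np);

      vec zP;
      const mat GPP = G.submat(P, P);
      const vec gP = g(P);
      const bool ok = solve(zP, GPP, gP,
                            solve_opts::no_approx + solve_opts::likely_sympd);
      if (!ok) zP = pinv(GPP) * gP;

      vec z(r, fill::zeros);
      z(P) = zP;

      bool feasible = true;
      for (uword idx = 0; idx < np; ++idx) {
        if (z(P(idx)) <= 0) { feasible = false; break; }
      }
      if (feasible) {
        x = z;
        break;
      }

      // step from x toward z until the first passive coordinate hits zero
      double alpha = datum::inf;
      for (uword idx = 0; idx < np; ++idx) {
        const uword j = P(idx);
        if (z(j) <= 0 && x(j) - z(j) > 0) {
          const double a = x(j) / (x(j) - z(j));
          if (a < alpha) alpha = a;
        }
      }
      if (!std::isfinite(alpha) || alpha < 0) alpha = 0.0;
      if (alpha > 1) alpha = 1.0;
      x += alpha * (z - x);
      for (uword idx = 0; idx < np; ++idx) {
        const uword j = P(idx);
        if (x(j) <= 1e-12) {
          x(j) = 0.0;
          passive[j] = false;
        }
      }
    }
    w = g - G * x;
  }
  return x;
}

//' Multi right-hand-side non-negative least squares (internal kernel).
//'
//' @param A design matrix, q x r
//' @param B targets, q x s (each column an independent RHS)
//' @param tol_rel KKT tolerance, scaled internally by max|A'B|
//' @return r x s non-negative solution matrix
//' @keywords internal
// [[Rcpp::export(name = ".nnls_multi_cpp")]]
arma::mat nnls_multi_cpp(const arma::mat& A, const arma::mat& B,
                         const double tol_rel = 1e-10) {
  const mat G = A.t() * A;
  const mat AtB = A.t() * B;
  double scale = AtB.n_elem > 0 ? abs(AtB).max() : 1.0;
  if (!(scale > 0)) scale = 1.0;
  const double tol = tol_rel * scale;

  mat X(A.n_cols, B.n_cols);
  for (uword j = 0; j < B.n_cols; ++j)
    X.col(j) = nnls_one(G, AtB.col(j), tol);
  return X;
}
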