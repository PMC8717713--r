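// Lawson-Hanson active-set non-negative least squares.
// Used for voxel-level residue mapping (hundreds of thousands of small
// solves per experiment), for monotone residue fitting, and for the
// GCV objective in backward elimination.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static vec nnls_one(const mat& A, const vec& b) {
  const uword k = A.n_cols;
  vec x(k, fill::zeros);
  std::vector<bool> passive(k, false);
  vec w = A.t() * b;                    // gradient at x = 0
  const double tol = 1e-12 * std::max(1.0, norm(w, "inf"));
  uword n_pass = 0;
  const uword max_outer = 3 * k + 10;

  for (uword outer = 0; outer < max_outer; ++outer) {
    // most violated KKT multiplier among the active (zero) set
    int jmax = -1;
    double wmax = tol;
    for (uword j = 0; j < k; ++j) {
      if (!passive[j] && w(j) > wmax) { wmax = w(j); jmax = (int)j; }
    }
    if (jmax < 0) break;
    passive[jmax] = true;
    ++n_pass;

    // inner loop: restricted least squares with backtracking
    for (uword inner = 0; inner < max_outer; ++inner) {
      uvec P(n_pass);
      uword c = 0;
      for (uword j = 0; j < k; ++j) if (passive[j]) P(c++) = j;
      mat AP = A.cols(P);
      vec z;
      bool ok = solve(z, AP, b, solve_opts::fast + solve_opts::no_approx);
      if (!ok) z = pinv(AP) * b;

      bool all_pos = true;
      for (uword m = 0; m < n_pass; ++m)
        if (z(m) <= 0) { all_pos = false; break; }
      if (all_pos) {
        x.zeros();
        for (uword m = 0; m < n_pass; ++m) x(P(m)) = z(m);
        break;
      }
      // step toward z until the first coefficient hits zero
      double alpha = datum::inf;
      for (uword m = 0; m < n_pass; ++m) {
        if (z(m) <= 0) {
          double a = x(P(m)) / (x(P(m)) - z(m));
          if (a < alpha) alpha = a;
        }
      }
      for (uword m = 0; m < n_pass; ++m)
        x(P(m)) += alpha * (z(m) - x(P(m)));
      for (uword m = 0; m < n_pass; ++m) {
        if (passive[P(m)] && x(P(m)) <= 1e-14) {
          x(P(m)) = 0.0;
          passive[P(m)] = false;
          --n_pass;
        }
      }
      if (n_pass == 0) break;
    }
    w = A.t() * (b - A * x);
  }
  return x;
}

//' @noRd
// [[Rcpp::export(name = ".nnls_multi")]]
arma::mat nnls_multi(const arma::mat& A, const arma::mat& B) {
  mat X(A.n_cols, B.n_cols);
  for (uword i = 0; i < B.n_cols; ++i) X.col(i) = nnls_one(A, B.col(i));
  return X;
}
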