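#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Cyclic coordinate descent for the per-voxel elastic problem
//   min_a 0.5 * ||s_j - D a||_2^2 + lambda * ||a||_1
// S is voxels x time, D is time x n_atoms with (near) unit-norm columns.
// Dead atoms (all-zero columns) are left with zero coefficients.
// Returns the code matrix (n_atoms x voxels), the per-voxel objective at the
// solution, and the number of full sweeps used per voxel.
// [[Rcpp::export]]
Rcpp::List cd_sparse_code(const arma::mat& S, const arma::mat& D,
                          const double lambda, const double tol,
                          const int max_sweeps) {
  const uword V = S.n_rows;
  const uword n = D.n_cols;

  const mat G = D.t() * D;   // n x n Gram matrix
  const mat B = D.t() * S.t();  // n x V correlations of atoms with signals
  const vec g = G.diag();

  mat A(n, V, fill::zeros);
  vec obj(V);
  ivec sweeps(V);

  for (uword j = 0; j < V; ++j) {
    vec a(n, fill::zeros);
    const vec b = B.col(j);
    vec Ga(n, fill::zeros);  // running G * a
    int sw = 0;
    for (; sw < max_sweeps; ++sw) {
      double delta = 0.0;
      for (uword k = 0; k < n; ++k) {
        if (g(k) <= 0.0) continue;  // dead atom
        const double old = a(k);
        const double r = b(k) - Ga(k) + g(k) * old;
        double anew = 0.0;
        if (r > lambda) anew = (r - lambda) / g(k);
        else if (r < -lambda) anew = (r + lambda) / g(k);
        const double d = anew - old;
        if (d != 0.0) {
          Ga += G.col(k) * d;
          a(k) = anew;
          const double ad = std::abs(d);
          if (ad > delta) delta = ad;
        }
      }
      if (delta < tol) { ++sw; break; }
    }
    A.col(j) = a;
    const double ss = dot(S.row(j), S.row(j));
    obj(j) = 0.5 * ss - dot(a, b) + 0.5 * dot(a, Ga) + lambda * norm(a, 1);
    sweeps(j) = sw;
  }

  return Rcpp::List::create(Rcpp::Named("codes") = A,
                            Rcpp::Named("objective") = obj,
                            Rcpp::Named("sweeps") = sweeps);
}
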