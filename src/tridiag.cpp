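#include <Rcpp.h>
using namespace Rcpp;

// Thomas algorithm for a tridiagonal system with (possibly) multiple
// right-hand sides sharing the same matrix. lower[0] and upper[n-1] are
// ignored. Used by the implicit vertical-diffusion solve, where the matrix
// is strictly diagonally dominant, so no pivoting is required.
// [[Rcpp::export(name = ".solve_tridiag")]]
NumericMatrix solve_tridiag(NumericVector lower, NumericVector diag,
                            NumericVector upper, NumericMatrix rhs) {
  const int n = diag.size();
  if (lower.size() != n || upper.size() != n || rhs.nrow() != n)
    stop("tridiagonal system dimensions do not match");
  const int m = rhs.ncol();
  std::vector<double> cp(n);
  NumericMatrix x(n, m);

  double denom = diag[0];
  if (denom == 0.0) stop("singular tridiagonal system (degenerate grid?)");
  cp[0] = upper[0] / denom;
  for (int j = 0; j < m; ++j) x(0, j) = rhs(0, j) / denom;
  for (int i = 1; i < n; ++i) {
    denom = diag[i] - lower[i] * cp[i - 1];
    if (denom == 0.0) stop("singular tridiagonal system (degenerate grid?)");
    cp[i] = upper[i] / denom;
    for (int j = 0; j < m; ++j)
      x(i, j) = (rhs(i, j) - lower[i] * x(i - 1, j)) / denom;
  }
  for (int i = n - 2; i >= 0; --i)
    for (int j = 0; j < m; ++j)
      x(i, j) -= cp[i] * x(i + 1, j);
  return x;
}
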