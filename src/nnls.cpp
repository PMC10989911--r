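// Nonnegative least squares for many right-hand sides, via block principal
// pivoting on the normal equations (Kim & Park style). Systems here are tiny
// (k = number of strains, <= ~12) but numerous (one per gene family), so the
// per-column loop lives in C++.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static vec solve_passive(const mat& C, const vec& d, const uvec& F) {
  // solve C[F,F] x_F = d[F]; tiny ridge guards rank-deficient passive sets
  mat CFF = C.submat(F, F);
  CFF.diag() += 1e-12 * (trace(CFF) / CFF.n_rows + 1.0);
  vec xF;
  if (!solve(xF, CFF, d.elem(F), solve_opts::likely_sympd + solve_opts::no_approx)) {
    xF = pinv(CFF) * d.elem(F);
  }
  return xF;
}

// Solve min_{X >= 0} ||A X - B||_F^2 given C = A'A (k x k) and D = A'B (k x n).
// Returns k x n nonnegative X.
// [[Rcpp::export]]
arma::mat nnls_bpp(const arma::mat& C, const arma::mat& D) {
  const uword k = C.n_rows, n = D.n_cols;
  mat X(k, n, fill::zeros);

  for (uword j = 0; j < n; ++j) {
    vec d = D.col(j);
    // passive/active bookkeeping
    std::vector<bool> passive(k, false);
    vec x(k, fill::zeros);
    vec y = -d;               // y = C x - d, x = 0
    int backup = 3;           // full-exchange credits before single swaps
    uword ninf_prev = k + 1;
    const uword max_pivot = 10 * k + 50;

    for (uword it = 0; it <= max_pivot; ++it) {
      // infeasible indices
      uvec viol(k);
      uword nv = 0;
      for (uword i = 0; i < k; ++i) {
        if (passive[i] ? (x(i) < -1e-12) : (y(i) < -1e-12)) viol(nv++) = i;
      }
      if (nv == 0) break;
      viol.resize(nv);

      if (nv < ninf_prev) { ninf_prev = nv; backup = 3; }
      else if (backup > 0) { --backup; }

      if (backup > 0) {
        for (uword t = 0; t < nv; ++t) passive[viol(t)] = !passive[viol(t)];
      } else {
        // Murty-style fallback: flip only the largest violating index
        passive[viol(nv - 1)] = !passive[viol(nv - 1)];
      }

      uvec F(k); uword nf = 0;
      for (uword i = 0; i < k; ++i) if (passive[i]) F(nf++) = i;
      x.zeros(); y.zeros();
      if (nf > 0) {
        F.resize(nf);
        vec xF = solve_passive(C, d, F);
        x.elem(F) = xF;
        y = C.cols(F) * xF - d;
        y.elem(F).zeros();
      } else {
        y = -d;
      }
    }
    x.transform([](double v) { return v < 0 ? 0.0 : v; });
    X.col(j) = x;
  }
  return X;
}
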