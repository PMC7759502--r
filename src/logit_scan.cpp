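// Fast iteratively reweighted least squares (IRLS) logistic fits for the
// per-feature association scan and its phenotype-permutation null.
// The Wald statistic reported here matches stats::glm(family = binomial)
// to numerical precision (checked in the test suite). The inner loops are
// hand-accumulated because the permutation framework refits B x m models.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct IrlsWork {
  arma::vec beta, delta, score, eta, tmp;
  arma::mat AtWA, L;
  double var_x;  // (A'WA)^{-1} element for the feature coefficient
  void resize(arma::uword n, arma::uword p) {
    beta.set_size(p); delta.set_size(p); score.set_size(p); tmp.set_size(p);
    eta.set_size(n); AtWA.set_size(p, p); L.set_size(p, p);
  }
};

// In-place Cholesky of the lower triangle of S (p is small: covariate
// count + 2), avoiding LAPACK call overhead in the B x m refit loop.
static bool chol_small(const arma::mat& S, arma::mat& L, arma::uword p) {
  for (arma::uword j = 0; j < p; ++j) {
    double d = S(j, j);
    for (arma::uword k = 0; k < j; ++k) d -= L(j, k) * L(j, k);
    if (d <= 0.0 || !std::isfinite(d)) return false;
    const double lj = std::sqrt(d);
    L(j, j) = lj;
    for (arma::uword i = j + 1; i < p; ++i) {
      double s = S(i, j);
      for (arma::uword k = 0; k < j; ++k) s -= L(i, k) * L(j, k);
      L(i, j) = s / lj;
    }
  }
  return true;
}

// Solve L L' x = b given the Cholesky factor.
static void chol_solve(const arma::mat& L, const double* b, arma::vec& tmp,
                       arma::vec& x, arma::uword p) {
  for (arma::uword i = 0; i < p; ++i) {
    double s = b[i];
    for (arma::uword k = 0; k < i; ++k) s -= L(i, k) * tmp(k);
    tmp(i) = s / L(i, i);
  }
  for (arma::uword ii = p; ii-- > 0;) {
    double s = tmp(ii);
    for (arma::uword k = ii + 1; k < p; ++k) s -= L(k, ii) * x(k);
    x(ii) = s / L(ii, ii);
  }
}

// One logistic Newton/IRLS fit. A: n x p design, column-major (first column
// intercept, second the feature), y in {0,1}. Returns false on a
// numerically singular system; on success w.beta holds the estimate and
// w.var_x the Wald variance of the feature coefficient.
static bool irls_fit(const double* A, arma::uword n, arma::uword p,
                     const double* y, IrlsWork& w) {
  w.beta.zeros();
  {  // warm start at the null intercept
    double ybar = 0.0;
    for (arma::uword i = 0; i < n; ++i) ybar += y[i];
    ybar /= n;
    if (ybar > 0.0 && ybar < 1.0) w.beta(0) = std::log(ybar / (1.0 - ybar));
  }
  for (int it = 0; it < 35; ++it) {
    // eta = A * beta
    w.eta.zeros();
    for (arma::uword j = 0; j < p; ++j) {
      const double bj = w.beta(j);
      if (bj == 0.0) continue;
      const double* col = A + j * n;
      for (arma::uword i = 0; i < n; ++i) w.eta(i) += bj * col[i];
    }
    // score = A'(y - mu); AtWA = A' W A with W = diag(mu (1 - mu))
    w.AtWA.zeros();
    w.score.zeros();
    for (arma::uword i = 0; i < n; ++i) {
      double mu = 1.0 / (1.0 + std::exp(-w.eta(i)));
      if (mu < 1e-10) mu = 1e-10;
      else if (mu > 1.0 - 1e-10) mu = 1.0 - 1e-10;
      const double wi = mu * (1.0 - mu);
      const double ri = y[i] - mu;
      for (arma::uword j = 0; j < p; ++j) {
        const double aij = A[j * n + i];
        w.score(j) += aij * ri;
        const double waij = wi * aij;
        for (arma::uword k = j; k < p; ++k)
          w.AtWA(k, j) += waij * A[k * n + i];
      }
    }
    if (!chol_small(w.AtWA, w.L, p)) return false;
    chol_solve(w.L, w.score.memptr(), w.tmp, w.delta, p);
    w.beta += w.delta;
    if (arma::abs(w.delta).max() < 1e-9) break;
  }
  // var of the feature coefficient: column 1 of (A'WA)^{-1} via e_1 solve
  w.score.zeros();
  w.score(1) = 1.0;
  chol_solve(w.L, w.score.memptr(), w.tmp, w.delta, p);
  w.var_x = w.delta(1);
  return std::isfinite(w.var_x);
}

// -log10 of the two-sided Wald P for a z-statistic, computed in log space
// so extreme statistics do not underflow.
static double wald_neglog10p(double zstat) {
  double lp = R::pnorm(std::fabs(zstat), 0.0, 1.0, /*lower*/ 0, /*log_p*/ 1);
  double l10 = -(std::log(2.0) + lp) / std::log(10.0);
  return l10 < 0.0 ? 0.0 : l10;
}

// Assemble the per-feature design [1, x_j, C] (column-major), n x (q + 2).
static void fill_design(arma::mat& A, const arma::mat& X, const arma::mat& C,
                        arma::uword j) {
  A.col(0).ones();
  A.col(1) = X.col(j);
  if (C.n_cols > 0) A.cols(2, C.n_cols + 1) = C;
}

// Per-feature logistic scan: phenotype ~ feature + covariates.
// X: n x m feature matrix (columns are features, already transformed);
// C: n x q covariate matrix (q may be 0); y: n-vector in {0,1}.
// [[Rcpp::export]]
List cpp_logit_scan(const arma::mat& X, const arma::mat& C,
                    const arma::vec& y) {
  const arma::uword n = X.n_rows, m = X.n_cols, q = C.n_cols, p = q + 2;
  arma::vec beta_out(m), se_out(m), l10p_out(m);
  arma::mat A(n, p);
  IrlsWork w;
  w.resize(n, p);
  for (arma::uword j = 0; j < m; ++j) {
    fill_design(A, X, C, j);
    bool degenerate = (X.col(j).max() - X.col(j).min()) < 1e-12;
    if (degenerate || !irls_fit(A.memptr(), n, p, y.memptr(), w) ||
        w.var_x <= 0.0) {
      beta_out(j) = NA_REAL;
      se_out(j) = NA_REAL;
      l10p_out(j) = 0.0;
      continue;
    }
    double se = std::sqrt(w.var_x);
    beta_out(j) = w.beta(1);
    se_out(j) = se;
    l10p_out(j) = wald_neglog10p(w.beta(1) / se);
  }
  return List::create(_["beta"] = beta_out, _["se"] = se_out,
                      _["neglog10p"] = l10p_out);
}

// Phenotype-permutation null scan. perm: B x n matrix of 1-based sample
// indices; row b defines the permuted phenotype y[perm[b, ]]. Covariates
// stay with the samples, so each permuted scan retains covariate
// adjustment. Returns a B x m matrix of -log10 P sorted in descending
// order per row.
// [[Rcpp::export]]
arma::mat cpp_perm_scan(const arma::mat& X, const arma::mat& C,
                        const arma::vec& y, const arma::imat& perm) {
  const arma::uword n = X.n_rows, m = X.n_cols, q = C.n_cols, p = q + 2;
  const arma::uword B = perm.n_rows;
  if (perm.n_cols != n) stop("permutation index matrix must have n columns");
  arma::mat out(B, m);
  // Per-feature designs are fixed across permutations; only y changes.
  arma::cube designs(n, p, m);
  std::vector<bool> degenerate(m);
  for (arma::uword j = 0; j < m; ++j) {
    arma::mat A(n, p);
    fill_design(A, X, C, j);
    designs.slice(j) = A;
    degenerate[j] = (X.col(j).max() - X.col(j).min()) < 1e-12;
  }
  arma::vec yb(n);
  std::vector<double> row(m);
  IrlsWork w;
  w.resize(n, p);
  for (arma::uword b = 0; b < B; ++b) {
    for (arma::uword i = 0; i < n; ++i) yb(i) = y(perm(b, i) - 1);
    for (arma::uword j = 0; j < m; ++j) {
      double l10p = 0.0;
      if (!degenerate[j] &&
          irls_fit(designs.slice(j).memptr(), n, p, yb.memptr(), w) &&
          w.var_x > 0.0) {
        l10p = wald_neglog10p(w.beta(1) / std::sqrt(w.var_x));
      }
      row[j] = l10p;
    }
    std::sort(row.begin(), row.end(), std::greater<double>());
    for (arma::uword j = 0; j < m; ++j) out(b, j) = row[j];
    if (b % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
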