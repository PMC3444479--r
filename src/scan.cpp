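// Penalized logistic likelihood engine for branch scanning.
//
// The permutation scan evaluates one logistic fit per (branch, permutation);
// everything on that hot path lives here.  Firth's bias-reduced fit follows
// the standard penalized-IRLS scheme (Jeffreys-prior penalty, modified score
// with hat diagonals); the plain fit is ordinary IRLS.  Both return the
// (penalized) log-likelihood at the optimum so the caller can form
// likelihood-ratio statistics.  The main path takes plain Newton steps with
// one Cholesky per iteration and defers all likelihood evaluation to the
// end; a slower step-halving path backs it up when Newton fails to settle
// (e.g. separation under the unpenalized fit).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double PCLAMP = 1e-10;

static inline double loglik(const vec& y, const vec& p) {
  vec pc = clamp(p, PCLAMP, 1.0 - PCLAMP);
  return accu(y % log(pc) + (1.0 - y) % log(1.0 - pc));
}

// (penalized) log-likelihood at beta; false when the information matrix is
// not positive definite
static bool pll_at(const mat& X, const vec& y, bool firth, const vec& beta,
                   double& out) {
  vec pr = 1.0 / (1.0 + exp(-(X * beta)));
  out = loglik(y, pr);
  if (firth) {
    vec w = clamp(pr % (1.0 - pr), PCLAMP, 0.25);
    mat XtWX = X.t() * (X.each_col() % w);
    mat R;
    if (!chol(R, XtWX)) return false;
    out += accu(log(R.diag()));
  }
  return std::isfinite(out);
}

// slow, safe path: penalized IRLS with step-halving on the likelihood
static double fit_robust(const mat& X, const vec& y, bool firth,
                         vec& beta, bool& ok,
                         int maxit = 30, double tol = 1e-6, int maxhs = 12) {
  ok = true;
  const uword p = X.n_cols;
  beta = zeros<vec>(p);
  double ll_cur;
  if (!pll_at(X, y, firth, beta, ll_cur)) { ok = false; return NA_REAL; }

  for (int it = 0; it < maxit; ++it) {
    vec pr = 1.0 / (1.0 + exp(-(X * beta)));
    vec w = clamp(pr % (1.0 - pr), PCLAMP, 0.25);
    mat XtWX = X.t() * (X.each_col() % w);
    mat A;
    if (!inv_sympd(A, XtWX) && !inv(A, XtWX)) { ok = false; return NA_REAL; }
    vec resid = y - pr;
    if (firth) {
      mat XA = X * A;
      vec h = w % sum(XA % X, 1);
      resid += h % (0.5 - pr);
    }
    vec step = A * (X.t() * resid);
    double ll_new;
    vec cand = beta + step;
    int hs = 0;
    while ((!pll_at(X, y, firth, cand, ll_new) || ll_new < ll_cur - 1e-10)
           && hs < maxhs) {
      step *= 0.5;
      cand = beta + step;
      ++hs;
    }
    if (hs == maxhs && (!pll_at(X, y, firth, cand, ll_new) ||
                        ll_new < ll_cur - 1e-10))
      return ll_cur;  // no uphill step left: report current point
    beta = cand;
    ll_cur = ll_new;
    if (norm(step, "inf") < tol) break;
  }
  return ll_cur;
}

// fast path: undamped Newton on the (modified) score from a warm start;
// falls back to fit_robust on any sign of trouble.  The Jeffreys log-det
// term of the returned likelihood is taken from the last Newton iterate
// (one sub-tol step behind the final beta) -- a deterministic convention
// shared by every statistic this engine produces.
static double fit_logistic(const mat& X, const vec& y, bool firth,
                           vec& beta, bool& ok,
                           int maxit = 25, double tol = 1e-6) {
  ok = true;
  const uword p = X.n_cols;
  if (beta.n_elem != p || !beta.is_finite()) beta = zeros<vec>(p);
  bool converged = false;
  double logdet = 0.0;
  for (int it = 0; it < maxit; ++it) {
    vec pr = 1.0 / (1.0 + exp(-(X * beta)));
    vec w = clamp(pr % (1.0 - pr), PCLAMP, 0.25);
    mat XtWX = X.t() * (X.each_col() % w);
    mat R;
    if (!chol(R, XtWX)) return fit_robust(X, y, firth, beta, ok);
    mat Ri = inv(trimatu(R));            // p x p, trivial
    mat A = Ri * Ri.t();
    vec resid = y - pr;
    if (firth) {
      logdet = 2.0 * accu(log(R.diag()));
      mat XA = X * A;                    // h_i = w_i x_i' A x_i
      vec h = w % sum(XA % X, 1);
      resid += h % (0.5 - pr);
    }
    vec step = A * (X.t() * resid);
    beta += step;
    if (!beta.is_finite()) return fit_robust(X, y, firth, beta, ok);
    if (norm(step, "inf") < tol) { converged = true; break; }
  }
  if (!converged) return fit_robust(X, y, firth, beta, ok);
  vec eta = clamp(X * beta, -30.0, 30.0);
  double ll = accu(y % eta - log1p(exp(eta)));
  if (firth) ll += 0.5 * logdet;
  if (!std::isfinite(ll)) return fit_robust(X, y, firth, beta, ok);
  return ll;
}

// Scan a set of branch genotype columns against a fixed covariate design.
// Xcov: n x p design (intercept included); y: 0/1 outcome; G: n x m genotype
// matrix, NA allowed (subject not in the branch's network component).
// Returns observed LR statistics, fitted coefficient vectors (warm starts for
// the permutation pass), the allele log-odds, and the null log-likelihood.
// [[Rcpp::export]]
Rcpp::List cppBranchScan(const arma::mat& Xcov, const arma::vec& y,
                         const arma::mat& G, bool firth) {
  const uword n = Xcov.n_rows, p = Xcov.n_cols, m = G.n_cols;
  vec beta0 = zeros<vec>(p);
  bool ok0 = true;
  double ll0_full = fit_logistic(Xcov, y, firth, beta0, ok0);

  vec stats(m); stats.fill(NA_REAL);
  vec dir(m); dir.fill(NA_REAL);
  mat betas(p + 1, m, fill::zeros);
  for (uword j = 0; j < m; ++j) {
    uvec keep = find_finite(G.col(j));
    bool full = (keep.n_elem == n);
    mat X(full ? n : keep.n_elem, p + 1);
    vec yy;
    if (full) {
      X.cols(0, p - 1) = Xcov; X.col(p) = G.col(j); yy = y;
    } else {
      X.cols(0, p - 1) = Xcov.rows(keep); X.col(p) = G(keep, uvec{j}); yy = y(keep);
    }
    double ll0 = ll0_full;
    if (!full) {
      vec b0 = zeros<vec>(p); bool okr = true;
      ll0 = fit_logistic(X.cols(0, p - 1), yy, firth, b0, okr);
      if (!okr) continue;
    }
    vec g = X.col(p);
    if (g.max() - g.min() < 1e-12) continue;  // constant allele: degenerate
    vec b = zeros<vec>(p + 1);
    if (full && ok0) b.subvec(0, p - 1) = beta0;
    bool okf = true;
    double llf = fit_logistic(X, yy, firth, b, okf);
    if (!okf || !ok0 || !std::isfinite(llf) || !std::isfinite(ll0)) continue;
    stats(j) = std::max(0.0, 2.0 * (llf - ll0));
    dir(j) = b(p);
    betas.col(j) = b;
  }
  return Rcpp::List::create(
    Rcpp::Named("stat") = stats,
    Rcpp::Named("coef") = dir,
    Rcpp::Named("beta") = betas,
    Rcpp::Named("ll0") = ll0_full);
}

// Permutation pass.  perms is B x nt (1-based indices into the rows of G:
// the haplotype assignment each tested subject receives under the
// permutation); the permuted genotype for branch j is G(perm, j).
// warmBetas: (p+1) x m observed-fit coefficients used as warm starts.
// Returns a B x m matrix of LR statistics (NA where the fit is degenerate).
// [[Rcpp::export]]
arma::mat cppPermScan(const arma::mat& Xcov, const arma::vec& y,
                      const arma::mat& G, const arma::imat& perms,
                      bool firth, const arma::mat& warmBetas,
                      double ll0Full) {
  const uword n = Xcov.n_rows, p = Xcov.n_cols, m = G.n_cols, B = perms.n_rows;
  mat out(B, m); out.fill(NA_REAL);
  const bool anyNA = !G.is_finite();

  mat X(n, p + 1);
  X.cols(0, p - 1) = Xcov;

  for (uword b = 0; b < B; ++b) {
    uvec idx(n);
    for (uword i = 0; i < n; ++i) idx(i) = (uword)(perms(b, i) - 1);
    for (uword j = 0; j < m; ++j) {
      vec g = G(idx, uvec{j});
      uvec keep;
      bool full = true;
      if (anyNA) {
        keep = find_finite(g);
        full = (keep.n_elem == n);
      }
      bool okf = true;
      double llf, ll0 = ll0Full;
      if (full) {
        if (g.max() - g.min() < 1e-12) continue;
        X.col(p) = g;
        vec bb = warmBetas.col(j);
        llf = fit_logistic(X, y, firth, bb, okf);
      } else {
        if (keep.n_elem < 2) continue;
        mat Xs(keep.n_elem, p + 1);
        Xs.cols(0, p - 1) = Xcov.rows(keep);
        vec gs = g(keep);
        if (gs.max() - gs.min() < 1e-12) continue;
        Xs.col(p) = gs;
        vec yy = y(keep);
        vec b0 = zeros<vec>(p); bool okr = true;
        ll0 = fit_logistic(Xs.cols(0, p - 1), yy, firth, b0, okr);
        if (!okr) continue;
        vec bb = warmBetas.col(j);
        llf = fit_logistic(Xs, yy, firth, bb, okf);
      }
      if (okf && std::isfinite(llf) && std::isfinite(ll0))
        out(b, j) = std::max(0.0, 2.0 * (llf - ll0));
    }
  }
  return out;
}
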