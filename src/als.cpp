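// Alternating penalized least squares for the latent-component G-by-E model,
// plus the phenotype-permutation loop. Inputs arrive standardized from R:
// X columns and e have mean 0 and sum of squares N, y is centered.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// Solve (A + diag(ridge)) x = b, falling back to pinv for singular systems.
vec ridge_solve(const mat& XtX, const vec& Xty, const vec& ridge) {
  mat A = XtX;
  A.diag() += ridge;
  vec out;
  bool ok = solve(out, A, Xty, solve_opts::no_approx);
  if (!ok) out = pinv(A) * Xty;
  return out;
}

struct AlsResult {
  vec w;
  vec beta;     // b1, b2, b12, intercept, covariate coefficients
  vec trace;
  bool converged;
  int n_iter;
  bool degenerate;
};

// Objective: SS(y - yhat) + lambda*(SS(w) + w_E^2) + lambda_B*SS(B),
// with w_E fixed at 1 (e is the standardized environment) and unnormalized
// latents g = Xw, r = g*e. The linear predictor carries an unpenalized
// intercept (r has nonzero mean, being a product of centered variables).
// Constraints sum g^2 = sum r^2 = N are applied as an output convention in
// R (joint rescaling leaves yhat invariant).
AlsResult als_engine(const vec& y, const mat& X, const vec& e, const mat& C,
                     double lambda, bool penalize_b, const vec& w0,
                     double tol, int max_iter) {
  const uword N = X.n_rows, K = X.n_cols, P = C.n_cols;
  const double lambda_b = penalize_b ? lambda : 0.0;

  AlsResult res;
  res.w = w0;
  res.beta = zeros<vec>(4 + P);
  res.converged = false;
  res.degenerate = false;
  res.n_iter = 0;

  std::vector<double> trace;
  trace.reserve(64);

  mat L(N, 4 + P);
  L.col(1) = e;
  L.col(3).ones();                    // intercept
  if (P > 0) L.cols(4, 3 + P) = C;
  vec bridge(4 + P, fill::value(lambda_b));
  bridge(3) = 0.0;                    // intercept unpenalized
  const vec wridge(K, fill::value(lambda));

  double phi_prev = datum::inf;
  vec g = X * res.w;

  for (int it = 1; it <= max_iter; ++it) {
    if (norm(g) < 1e-12 * std::sqrt((double) N)) {
      res.degenerate = true;
      break;
    }
    // (a) path coefficients given latents
    L.col(0) = g;
    L.col(2) = g % e;
    res.beta = ridge_solve(L.t() * L, L.t() * y, bridge);

    // (b) SNP weights given coefficients: y is linear in w with design
    // columns x_k * (b1 + b12 * e)
    const double b1 = res.beta(0), b2 = res.beta(1), b12 = res.beta(2);
    const double b0 = res.beta(3);
    if (std::fabs(b1) + std::fabs(b12) > 1e-14) {
      vec scale = b1 + b12 * e;
      mat D = X.each_col() % scale;
      vec target = y - b2 * e - b0;
      if (P > 0) target -= C * res.beta.subvec(4, 3 + P);
      res.w = ridge_solve(D.t() * D, D.t() * target, wridge);
    }

    g = X * res.w;
    vec resid = y - b1 * g - b2 * e - b12 * (g % e) - b0;
    if (P > 0) resid -= C * res.beta.subvec(4, 3 + P);
    vec bpen = res.beta; bpen(3) = 0.0;
    double phi = dot(resid, resid)
      + lambda * (dot(res.w, res.w) + 1.0)
      + lambda_b * dot(bpen, bpen);
    trace.push_back(phi);
    res.n_iter = it;

    if (!std::isfinite(phi)) Rcpp::stop("non-finite objective during ALS");
    if (std::fabs(phi - phi_prev) / (1.0 + phi_prev) < tol) {
      res.converged = true;
      break;
    }
    phi_prev = phi;
  }

  res.trace = vec(trace);
  return res;
}

// Interaction coefficient on the reporting scale (sum r^2 = N): the raw
// coefficient absorbs the norm of the unnormalized interaction latent.
double beta12_normalized(const AlsResult& fit, const mat& X, const vec& e) {
  vec r = (X * fit.w) % e;
  double N = (double) X.n_rows;
  return fit.beta(2) * std::sqrt(dot(r, r) / N);
}

// Reduced (no-interaction) ALS fit: y ~ b1*g + b2*e + b0 + C*bc with
// g = Xw, same penalties as the full model. Supplies the fitted values and
// residuals for residual-permutation (Freedman-Lane) null generation.
vec reduced_fitted(const vec& y, const mat& X, const vec& e, const mat& C,
                   double lambda, bool penalize_b, const vec& w0,
                   double tol, int max_iter) {
  const uword N = X.n_rows, K = X.n_cols, P = C.n_cols;
  const double lambda_b = penalize_b ? lambda : 0.0;

  vec w = w0;
  mat L(N, 3 + P);
  L.col(1) = e;
  L.col(2).ones();
  if (P > 0) L.cols(3, 2 + P) = C;
  vec bridge(3 + P, fill::value(lambda_b));
  bridge(2) = 0.0;
  const vec wridge(K, fill::value(lambda));

  vec beta(3 + P, fill::zeros);
  double phi_prev = datum::inf;
  vec g = X * w;
  for (int it = 1; it <= max_iter; ++it) {
    if (norm(g) < 1e-12 * std::sqrt((double) N)) break;
    L.col(0) = g;
    beta = ridge_solve(L.t() * L, L.t() * y, bridge);
    const double b1 = beta(0), b2 = beta(1), b0 = beta(2);
    if (std::fabs(b1) > 1e-14) {
      mat D = X * b1;
      vec target = y - b2 * e - b0;
      if (P > 0) target -= C * beta.subvec(3, 2 + P);
      w = ridge_solve(D.t() * D, D.t() * target, wridge);
    }
    g = X * w;
    vec resid = y - b1 * g - b2 * e - b0;
    if (P > 0) resid -= C * beta.subvec(3, 2 + P);
    vec bpen = beta; bpen(2) = 0.0;
    double phi = dot(resid, resid) + lambda * (dot(w, w) + 1.0)
      + lambda_b * dot(bpen, bpen);
    if (std::fabs(phi - phi_prev) / (1.0 + phi_prev) < tol) break;
    phi_prev = phi;
  }
  vec fit = beta(0) * g + beta(1) * e + beta(2) * ones<vec>(N);
  if (P > 0) fit += C * beta.subvec(3, 2 + P);
  return fit;
}

// Multi-start wrapper: one ALS run per column of W0, keep the lowest
// final objective (the bilinear objective can have local optima).
AlsResult als_best(const vec& y, const mat& X, const vec& e, const mat& C,
                   double lambda, bool penalize_b, const mat& W0,
                   double tol, int max_iter) {
  AlsResult best;
  best.degenerate = true;
  double best_phi = datum::inf;
  for (uword s = 0; s < W0.n_cols; ++s) {
    AlsResult fit = als_engine(y, X, e, C, lambda, penalize_b, W0.col(s),
                               tol, max_iter);
    if (fit.degenerate || fit.trace.n_elem == 0) continue;
    double phi = fit.trace(fit.trace.n_elem - 1);
    if (phi < best_phi) {
      best = fit;
      best_phi = phi;
    }
  }
  return best;
}

}  // namespace

// [[Rcpp::export(name = ".als_cpp")]]
Rcpp::List als_cpp(const arma::vec& y, const arma::mat& X, const arma::vec& e,
                   const arma::mat& C, double lambda, bool penalize_b,
                   const arma::mat& w0, double tol, int max_iter) {
  AlsResult fit = als_best(y, X, e, C, lambda, penalize_b, w0, tol, max_iter);
  if (fit.degenerate) Rcpp::stop("degenerate gene component: X %*% w is zero");
  return Rcpp::List::create(
    Rcpp::Named("w") = fit.w,
    Rcpp::Named("beta") = fit.beta,
    Rcpp::Named("trace") = fit.trace,
    Rcpp::Named("converged") = fit.converged,
    Rcpp::Named("n_iter") = fit.n_iter);
}

// [[Rcpp::export(name = ".reduced_fitted_cpp")]]
arma::vec reduced_fitted_cpp(const arma::vec& y, const arma::mat& X,
                             const arma::vec& e, const arma::mat& C,
                             double lambda, bool penalize_b,
                             const arma::vec& w0, double tol, int max_iter) {
  return reduced_fitted(y, X, e, C, lambda, penalize_b, w0, tol, max_iter);
}

// Permutation null for |beta12|: each replicate refits the full model on
// y_offset + y_perm[perm], so plain phenotype permutation (offset 0,
// y_perm = y) and residual permutation (offset = reduced fit, y_perm =
// reduced residuals) share one engine. Returns |beta12| (reporting scale)
// and a convergence flag per permutation.
// [[Rcpp::export(name = ".perm_beta12_cpp")]]
Rcpp::List perm_beta12_cpp(const arma::vec& y_offset, const arma::vec& y_perm,
                           const arma::mat& X,
                           const arma::vec& e, const arma::mat& C,
                           double lambda, bool penalize_b, const arma::mat& w0,
                           double tol, int max_iter, const arma::umat& perm) {
  const uword B = perm.n_rows;
  vec stat(B);
  uvec conv(B);
  for (uword b = 0; b < B; ++b) {
    vec yb = y_offset + y_perm(perm.row(b).t());
    AlsResult fit = als_best(yb, X, e, C, lambda, penalize_b, w0, tol, max_iter);
    if (fit.degenerate) {
      stat(b) = datum::nan;
      conv(b) = 0;
    } else {
      stat(b) = std::fabs(beta12_normalized(fit, X, e));
      conv(b) = fit.converged ? 1 : 0;
    }
  }
  return Rcpp::List::create(Rcpp::Named("stat") = stat,
                            Rcpp::Named("converged") = conv);
}

// Fast SNP-level interaction scans used by the permutation nulls of the
// p-value-combination tests: for one design per SNP (intercept, x, z, x*z,
// covariates) and many phenotype columns, t-test p-values for the x*z term.
// [[Rcpp::export(name = ".snp_interaction_pvals_cpp")]]
arma::mat snp_interaction_pvals_cpp(const arma::mat& Y, const arma::mat& X,
                                    const arma::vec& z, const arma::mat& C) {
  const uword N = X.n_rows, K = X.n_cols, R = Y.n_cols, P = C.n_cols;
  mat out(R, K);
  for (uword k = 0; k < K; ++k) {
    mat D(N, 4 + P, fill::ones);
    D.col(1) = X.col(k);
    D.col(2) = z;
    D.col(3) = X.col(k) % z;
    if (P > 0) D.cols(4, 3 + P) = C;
    mat Q, Rm;
    if (!qr_econ(Q, Rm, D) || std::fabs(Rm(3, 3)) < 1e-10 * norm(D.col(3))) {
      out.col(k).fill(1.0);  // collinear design
      continue;
    }
    mat QtY = Q.t() * Y;
    mat coefs;
    if (!solve(coefs, trimatu(Rm), QtY)) {
      out.col(k).fill(1.0);
      continue;
    }
    // unscaled variance of the interaction coefficient: [ (R'R)^-1 ]_{3,3}
    mat RtRinv = inv(trimatu(Rm));
    double v33 = dot(RtRinv.row(3), RtRinv.row(3));
    double df = (double) N - (double)(4 + P);
    for (uword r = 0; r < R; ++r) {
      double rss = dot(Y.col(r), Y.col(r)) - dot(QtY.col(r), QtY.col(r));
      double sigma2 = rss / df;
      double tval = coefs(3, r) / std::sqrt(sigma2 * v33);
      out(r, k) = 2.0 * R::pt(std::fabs(tval), df, 0, 0);
    }
  }
  return out;
}
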