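#' Fit the latent-component gene-environment interaction model
#'
#' Collapses all SNPs of a gene into one latent gene component
#' \eqn{g_i = \sum_k w_k x_{ik}} and forms a latent interaction component
#' \eqn{r_i = g_i e_i} with the (standardized) environment \eqn{e_i}. The
#' phenotype model is
#' \deqn{y_i = \beta_1 g_i + \beta_2 e_i + \beta_{12} r_i + \sum_p \beta_p c_{ip} + \epsilon_i,}
#' estimated by alternating ridge-penalized least squares under the
#' standardization constraints \eqn{\sum_i g_i^2 = \sum_i e_i^2 = \sum_i r_i^2 = N}.
#' The penalized objective is
#' \deqn{\phi = SS(y - \hat y) + \lambda_S SS(W) + \lambda_S SS(B),}
#' where \eqn{SS} is the sum of squares, \eqn{W} the component weights and
#' \eqn{B} the path coefficients. With a single environment variable the
#' constraint \eqn{\sum e_i^2 = N} forces \eqn{w_E = \pm\sqrt{N/\sum z_i^2}};
#' the positive root is taken, so \eqn{e} is simply the standardized
#' environment and the reported \eqn{w_E} carries no free information.
#'
#' Each alternating step (path coefficients given weights; weights given
#' coefficients) is an exact penalized least-squares solve, so the objective
#' trace is non-increasing. The constraints are imposed by a joint
#' back-normalization of weights and coefficients that leaves fitted values
#' unchanged; the reflection indeterminacy is resolved by flipping signs so
#' that \eqn{\sum_k w_k > 0} (or \eqn{w_1 > 0} on an exact tie).
#'
#' @param y numeric phenotype vector (quantitative trait).
#' @param X numeric genotype matrix, one column per SNP (additive 0/1/2
#'   coding or dosages); standardized internally.
#' @param z numeric environment vector; standardized internally.
#' @param covariates optional numeric matrix or data frame of adjustment
#'   covariates; standardized internally.
#' @param lambda ridge penalty \eqn{\lambda_S}. When `NULL` (default) it is
#'   chosen by [cv_lambda()] five-fold cross-validation over
#'   `lambda_grid`.
#' @param lambda_grid candidate penalties for cross-validation; default 15
#'   evenly spaced values on \[0, 0.5\].
#' @param folds number of cross-validation folds.
#' @param penalize_b if `TRUE` (default) the path coefficients \eqn{B} are
#'   penalized with the same \eqn{\lambda_S} as the weights; if `FALSE`
#'   only the weights are penalized.
#' @param init weight initializer. The alternating scheme is run from a
#'   small deterministic set of starts (the uniform \eqn{w_k = 1/\sqrt K}
#'   start plus coordinate and alternating-sign directions) and the lowest
#'   objective wins, since the bilinear objective can have local optima;
#'   `"random"` appends three seeded standard-normal starts.
#' @param tol convergence tolerance on the relative change of \eqn{\phi}.
#' @param max_iter maximum number of alternating iterations.
#' @param seed optional seed used for `init = "random"` and for the
#'   cross-validation fold split.
#'
#' The linear predictor carries an unpenalized intercept: the interaction
#' component \eqn{r = g e} is a product of centered variables and so has
#' nonzero mean, which the intercept absorbs (without it the model could
#' not reproduce even noiseless data exactly).
#'
#' @return An object of class `"gxe_fit"` with components `weights`
#'   (back-normalized SNP weights; `w_env` is the fixed environment weight),
#'   `coefficients` (`gene`, `env`, `interaction`, then covariates),
#'   `intercept`,
#'   `latents` (list `g`, `e`, `r`, each with sum of squares \eqn{N}),
#'   `lambda`, `cv` (a `"gxe_cv"` object when `lambda` was cross-validated),
#'   `objective` (per-iteration \eqn{\phi} trace), `converged`, `n_iter`,
#'   `fitted.values`, `residuals` and the standardization statistics needed
#'   by [predict.gxe_fit()].
#'
#' @examples
#' set.seed(1)
#' X <- matrix(rbinom(200 * 5, 2, 0.3), 200, 5)
#' z <- rnorm(200)
#' y <- 0.4 * scale(X)[, 1] + 0.3 * z + rnorm(200)
#' fit <- gxe_fit(y, X, z, lambda = 0.1)
#' coef(fit)
#' @seealso [gxe_perm_test()] for permutation inference on the interaction
#'   coefficient, [cv_lambda()], [gxe_scan()] for genome-wide scans.
#' @export
gxe_fit <- function(y, X, z, covariates = NULL, lambda = NULL,
                    lambda_grid = seq(0, 0.5, length.out = 15), folds = 5,
                    penalize_b = TRUE, init = c("uniform", "random"),
                    tol = 1e-6, max_iter = 1000, seed = NULL) {
  init <- match.arg(init)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  z <- as.numeric(z)
  N <- length(y)
  K <- ncol(X)
  stopifnot(nrow(X) == N, length(z) == N)
  if (anyNA(y) || anyNA(X) || anyNA(z))
    stop("missing values in y, X or z; run apply_qc()/validation first")

  C <- NULL
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    storage.mode(C) <- "double"
    stopifnot(nrow(C) == N)
    if (anyNA(C)) stop("missing values in covariates")
  }

  sx <- std_cols(X)
  if (any(sx$scale == 0)) stop("zero-variance genotype column(s): ",
                               paste(which(sx$scale == 0), collapse = ", "))
  sz <- std_vec(z)
  if (sz$scale == 0) stop("environment variable has zero variance")
  yc <- std_vec(y, scale = 1)   # center only
  sc <- NULL
  Cs <- matrix(0, N, 0)
  if (!is.null(C)) {
    sc <- std_cols(C)
    if (any(sc$scale == 0)) stop("zero-variance covariate column(s)")
    Cs <- sc$x
  }

  cv <- NULL
  if (is.null(lambda)) {
    cv <- cv_lambda(y, X, z, covariates, grid = lambda_grid, folds = folds,
                    penalize_b = penalize_b, tol = tol, max_iter = max_iter,
                    seed = seed)
    lambda <- cv$chosen
  }
  if (lambda < 0) stop("lambda must be non-negative")

  w0 <- make_starts(K, init = init, seed = seed)

  raw <- .als_cpp(yc$x, sx$x, sz$x, Cs, lambda, penalize_b, w0, tol, max_iter)
  if (!raw$converged)
    warning("ALS did not converge in ", max_iter, " iterations")

  out <- normalize_fit(raw, sx$x, sz$x, Cs, yc$x)
  names(out$weights) <- colnames(X) %||% paste0("snp", seq_len(K))
  cov_names <- colnames(C) %||% (if (is.null(C)) character(0)
                                 else paste0("cov", seq_len(ncol(C))))
  names(out$coefficients) <- c("gene", "env", "interaction", cov_names)

  structure(list(
    weights = out$weights,
    w_env = 1,
    coefficients = out$coefficients,
    intercept = out$intercept + yc$center,
    w_internal = as.numeric(raw$w),
    latents = out$latents,
    lambda = lambda,
    cv = cv,
    penalize_b = penalize_b,
    objective = as.numeric(raw$trace),
    converged = raw$converged,
    n_iter = raw$n_iter,
    fitted.values = out$fitted + yc$center,
    residuals = y - (out$fitted + yc$center),
    scaling = list(x_center = sx$center, x_scale = sx$scale,
                   z_center = sz$center, z_scale = sz$scale,
                   c_center = if (is.null(sc)) NULL else sc$center,
                   c_scale = if (is.null(sc)) NULL else sc$scale,
                   y_center = yc$center, r_scale = out$r_scale),
    data = list(y = yc$x, X = sx$x, e = sz$x, C = Cs),
    tol = tol, max_iter = max_iter, w0 = w0,
    N = N, K = K, call = match.call()
  ), class = "gxe_fit")
}

# Starting weights for the ALS runs. The bilinear objective can have local
# optima, so a small deterministic multi-start is used: the uniform start
# 1/sqrt(K) plus a few coordinate and alternating-sign directions (sign
# flips are redundant by the (w, beta1, beta12) -> -(w, beta1, beta12)
# symmetry). init = "random" appends three seeded standard-normal starts.
make_starts <- function(K, init = "uniform", seed = NULL) {
  starts <- list(rep(1 / sqrt(K), K))
  if (K > 1) {
    ek <- function(i) replace(numeric(K), i, 1)
    starts <- c(starts, list(ek(1), ek(K)))
    if (K > 2) starts <- c(starts, list(ek(ceiling(K / 2))))
    starts <- c(starts, list(rep_len(c(1, -1), K) / sqrt(K)))
  }
  if (init == "random") {
    if (!is.null(seed)) set.seed(seed)
    starts <- c(starts, lapply(1:3, function(i) stats::rnorm(K)))
  }
  W0 <- unique(do.call(cbind, starts), MARGIN = 2)
  matrix(W0, nrow = K)
}

# Back-normalize an ALS solution onto the constraint scale
# (sum g^2 = sum r^2 = N) and apply the sign convention. yhat is invariant.
normalize_fit <- function(raw, Xs, e, Cs, yc) {
  N <- nrow(Xs)
  w_u <- as.numeric(raw$w)
  beta_u <- as.numeric(raw$beta)
  g_u <- as.numeric(Xs %*% w_u)
  r_u <- g_u * e
  s_g <- sqrt(N / sum(g_u^2))
  w <- w_u * s_g
  g <- g_u * s_g
  b1 <- beta_u[1] / s_g
  ge <- g * e
  r_scale <- sqrt(N / sum(ge^2))
  r <- ge * r_scale
  b12 <- beta_u[3] / (s_g * r_scale)
  b2 <- beta_u[2]
  b0 <- beta_u[4]
  bc <- if (length(beta_u) > 4) beta_u[-(1:4)] else numeric(0)

  flip <- if (sum(w) != 0) sign(sum(w)) else sign(w[1])
  if (flip < 0) {
    w <- -w; g <- -g; r <- -r; b1 <- -b1; b12 <- -b12
  }

  fitted <- b1 * g + b2 * e + b12 * r + b0
  if (ncol(Cs) > 0) fitted <- fitted + as.numeric(Cs %*% bc)

  list(weights = w,
       coefficients = c(b1, b2, b12, bc),
       intercept = b0,
       latents = list(g = g, e = e, r = r),
       r_scale = r_scale,   # maps (X_std %*% weights) * e to the reported r
       fitted = as.numeric(fitted))
}

#' Construct standardized latent components from weights
#'
#' Builds the gene component \eqn{g = Xw}, environment component
#' \eqn{e = w_E z} and interaction component \eqn{r = g e} (elementwise),
#' each rescaled to satisfy its standardization constraint
#' \eqn{\sum g^2 = \sum e^2 = \sum r^2 = N}. The rescaling factors are
#' returned so the weights can be back-normalized
#' (`w * scale["g"]` reproduces `g` exactly).
#'
#' @param X standardized genotype block (columns mean 0, sum of squares N).
#' @param z standardized environment vector.
#' @param w numeric weight vector, one entry per column of `X`.
#' @param w_env environment weight (sign only matters; default 1).
#' @return list with `g`, `e`, `r` and `scale`, a named vector of the
#'   factors applied to `X %*% w`, `w_env * z` and `g * e` respectively.
#' @examples
#' X <- scale(matrix(rnorm(40), 20, 2)) * sqrt(20 / 19)
#' lat <- build_latents(X, scale(rnorm(20))[, 1], w = c(1, 1))
#' sum(lat$g^2)  # == 20
#' @export
build_latents <- function(X, z, w, w_env = 1) {
  X <- as.matrix(X)
  N <- nrow(X)
  stopifnot(length(w) == ncol(X), length(z) == N, is.finite(w_env))
  if (!all(is.finite(w))) stop("non-finite weights")
  g_raw <- as.numeric(X %*% w)
  if (sum(g_raw^2) < 1e-24 * N)
    stop("degenerate gene component: X %*% w is (numerically) zero")
  e_raw <- w_env * z
  if (sum(e_raw^2) == 0) stop("degenerate environment component")
  s_g <- sqrt(N / sum(g_raw^2))
  s_e <- sqrt(N / sum(e_raw^2))
  g <- g_raw * s_g
  e <- e_raw * s_e
  ge <- g * e
  s_r <- sqrt(N / sum(ge^2))
  list(g = g, e = e, r = ge * s_r,
       scale = c(g = s_g, e = s_e, r = s_r))
}

#' Penalized least-squares objective
#'
#' Evaluates \eqn{\phi = SS(y - \hat y) + \lambda_S SS(W) + \lambda_S SS(B)}
#' (or with the \eqn{SS(B)} term unpenalized when `penalize_b = FALSE`),
#' where \eqn{SS} is the plain sum of squares.
#'
#' @param y observed phenotype.
#' @param y_hat fitted values.
#' @param W component weight vector (include the environment weight if it is
#'   to be penalized).
#' @param B path coefficient vector.
#' @param lambda_s ridge penalty.
#' @param penalize_b whether \eqn{SS(B)} enters with weight `lambda_s`
#'   (default) or not at all.
#' @return scalar objective value.
#' @examples
#' objective_phi(c(1, 1), c(0, 0), W = 1, B = 2, lambda_s = 0.5)  # 4.5
#' @export
objective_phi <- function(y, y_hat, W, B, lambda_s, penalize_b = TRUE) {
  stopifnot(length(y) == length(y_hat))
  sum((y - y_hat)^2) + lambda_s * sum(W^2) +
    (if (penalize_b) lambda_s else 0) * sum(B^2)
}

#' Cross-validate the ridge penalty
#'
#' Five-fold (by default) cross-validation of \eqn{\lambda_S} over a grid of
#' 15 values spanning \[0, 0.5\]. For each candidate, the model is fitted on
#' the training folds and held-out phenotypes are predicted using the
#' fold-trained weights and coefficients, with all standardization statistics
#' taken from the training fold. The chosen penalty minimizes the mean
#' held-out squared prediction error; ties are broken toward the larger
#' penalty (more regularization).
#'
#' @inheritParams gxe_fit
#' @param grid candidate penalty values.
#' @return object of class `"gxe_cv"`: list with `grid`, `cv_error`,
#'   `chosen`, `folds` and the fold assignment `fold_id`.
#' @export
cv_lambda <- function(y, X, z, covariates = NULL,
                      grid = seq(0, 0.5, length.out = 15), folds = 5,
                      penalize_b = TRUE, tol = 1e-6, max_iter = 1000,
                      seed = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  z <- as.numeric(z)
  N <- length(y)
  if (N < folds) stop("need at least as many samples as folds")
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)

  if (!is.null(seed)) set.seed(seed)
  fold_id <- sample(rep(seq_len(folds), length.out = N))

  sse <- matrix(0, length(grid), folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    te <- !tr
    Xtr <- X[tr, , drop = FALSE]
    keep <- apply(Xtr, 2L, function(col) stats::var(col) > 0)
    if (!all(keep))
      message("cv_lambda: dropping ", sum(!keep),
              " zero-variance column(s) in fold ", f)
    if (!any(keep)) stop("all genotype columns constant within fold ", f)
    sx <- std_cols(Xtr[, keep, drop = FALSE])
    sz <- std_vec(z[tr])
    yc <- std_vec(y[tr], scale = 1)
    Cs_tr <- matrix(0, sum(tr), 0)
    sc <- NULL
    if (!is.null(C)) {
      sc <- std_cols(C[tr, , drop = FALSE])
      Cs_tr <- sc$x
    }
    Xte <- std_cols(X[te, keep, drop = FALSE], sx$center, sx$scale)$x
    ete <- std_vec(z[te], sz$center, sz$scale)$x
    Cte <- if (is.null(C)) matrix(0, sum(te), 0) else
      std_cols(C[te, , drop = FALSE], sc$center, sc$scale)$x

    # multi-start on the first grid value, then warm-start along the
    # lambda path (the solution moves continuously in lambda)
    w0 <- make_starts(sum(keep))
    for (i in seq_along(grid)) {
      raw <- .als_cpp(yc$x, sx$x, sz$x, Cs_tr, grid[i], penalize_b, w0,
                      tol, max_iter)
      w0 <- matrix(as.numeric(raw$w), ncol = 1)
      nf <- normalize_fit(raw, sx$x, sz$x, Cs_tr, yc$x)
      b <- nf$coefficients
      g_new <- as.numeric(Xte %*% nf$weights)
      r_new <- g_new * ete * nf$r_scale
      pred <- b[1] * g_new + b[2] * ete + b[3] * r_new + nf$intercept
      if (ncol(Cte) > 0) pred <- pred + as.numeric(Cte %*% b[-(1:3)])
      sse[i, f] <- sum((y[te] - (pred + yc$center))^2)
    }
  }
  cv_error <- rowSums(sse) / N
  best <- max(which(cv_error == min(cv_error)))
  structure(list(grid = grid, cv_error = cv_error, chosen = grid[best],
                 folds = folds, fold_id = fold_id),
            class = "gxe_cv")
}
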