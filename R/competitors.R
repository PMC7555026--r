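#' Single-SNP gene-environment interaction test
#'
#' Ordinary least squares of `y` on intercept, SNP, environment, SNP-by-
#' environment product and covariates; two-sided t-test p-value for the
#' product term. A collinear design (e.g. a constant SNP) returns p = 1
#' with a warning.
#'
#' @param y phenotype vector.
#' @param x single SNP (additive coding).
#' @param z environment vector.
#' @param covariates optional covariate matrix.
#' @return two-sided p-value for the interaction coefficient.
#' @export
snp_gxe_test <- function(y, x, z, covariates = NULL) {
  C <- if (is.null(covariates)) matrix(0, length(y), 0) else
    as.matrix(covariates)
  D <- cbind(1, x, z, x * z, C)
  if (qr(D)$rank < ncol(D)) {
    warning("collinear interaction design; returning p = 1")
    return(1)
  }
  p <- .snp_interaction_pvals_cpp(matrix(as.numeric(y)),
                                  matrix(as.numeric(x)),
                                  as.numeric(z), C)
  as.numeric(p[1, 1])
}

#' SNP-level interaction p-values for a gene
#'
#' Runs [snp_gxe_test()] for every SNP column and records the genotype
#' correlation matrix needed by the p-value combination tests.
#'
#' @param y phenotype vector.
#' @param X genotype matrix (one column per SNP).
#' @param z environment vector.
#' @param covariates optional covariate matrix.
#' @return object of class `"snp_gxe"`: list with `p_values` and
#'   `genotype_corr`.
#' @export
snp_gxe_pvalues <- function(y, X, z, covariates = NULL) {
  X <- as.matrix(X)
  C <- if (is.null(covariates)) matrix(0, length(y), 0) else
    as.matrix(covariates)
  p <- as.numeric(.snp_interaction_pvals_cpp(matrix(as.numeric(y)),
                                             X, as.numeric(z), C))
  structure(list(p_values = p, genotype_corr = safe_corr(X)),
            class = "snp_gxe")
}

# correlation matrix robust to zero-variance columns (treated as
# uncorrelated with everything)
safe_corr <- function(X) {
  sds <- apply(X, 2L, stats::sd)
  R <- diag(ncol(X))
  ok <- sds > 0
  if (sum(ok) > 1) R[ok, ok] <- stats::cor(X[, ok, drop = FALSE])
  R
}

#' Effective number of independent tests (eigenvalue method)
#'
#' The Li-Ji estimate: with eigenvalues \eqn{\lambda_i} of the correlation
#' matrix, \eqn{M_e = \sum_i [I(\lambda_i \ge 1) + (\lambda_i -
#' \lfloor\lambda_i\rfloor)]}. Equals K for independent tests and 1 for
#' perfectly correlated ones.
#'
#' @param corr symmetric correlation matrix.
#' @return effective number of tests, in \[1, K\].
#' @export
effective_tests <- function(corr) {
  corr <- as.matrix(corr)
  if (nrow(corr) == 1) return(1)
  ev <- abs(eigen(corr, symmetric = TRUE, only.values = TRUE)$values)
  # round away floating-point noise: an eigenvalue of 4 - 1e-15 must not
  # contribute a fractional part of ~1
  ev <- round(ev, 10)
  max(1, sum(ifelse(ev >= 1, 1, 0) + (ev - floor(ev))))
}

# GATES approximation of the correlation between two SNP-level p-values
# from the genotype correlation r (sixth-order polynomial of the original
# procedure).
gates_pcorr <- function(genotype_corr) {
  r <- genotype_corr
  rp <- 0.2982 * r^6 - 0.0127 * r^5 + 0.0588 * r^4 +
    0.0099 * r^3 + 0.6281 * r^2 - 0.0009 * r
  diag(rp) <- 1
  rp
}

#' Gene-level minimum-p interaction test
#'
#' \eqn{p = 1 - (1 - \min_j p_j)^{M_e}} with the effective number of tests
#' \eqn{M_e} estimated from the genotype correlation matrix by
#' [effective_tests()].
#'
#' @param results a [snp_gxe_pvalues()] object.
#' @return gene-level p-value.
#' @export
ge_minp <- function(results) {
  stopifnot(inherits(results, "snp_gxe"))
  me <- effective_tests(results$genotype_corr)
  min(1, max(0, 1 - (1 - min(results$p_values))^me))
}

#' Gene-level GATES (extended Simes) interaction test
#'
#' With SNP p-values sorted ascending, \eqn{p = \min_j M_e p_{(j)} /
#' M_{e(j)}}, where \eqn{M_{e(j)}} is the effective number of tests among
#' the top-\eqn{j} SNPs. By default the effective numbers come from the
#' p-value correlation matrix approximated from genotype correlations by
#' the GATES sixth-order polynomial; `corr = "genotype"` uses the genotype
#' correlation matrix directly.
#'
#' @param results a [snp_gxe_pvalues()] object.
#' @param corr `"polynomial"` (default) or `"genotype"`.
#' @return gene-level p-value.
#' @export
ge_gates <- function(results, corr = c("polynomial", "genotype")) {
  stopifnot(inherits(results, "snp_gxe"))
  corr <- match.arg(corr)
  R <- if (corr == "polynomial") gates_pcorr(results$genotype_corr) else
    results$genotype_corr
  ord <- order(results$p_values)
  ps <- results$p_values[ord]
  K <- length(ps)
  me_j <- vapply(seq_len(K), function(j)
    effective_tests(R[ord[seq_len(j)], ord[seq_len(j)], drop = FALSE]),
    numeric(1))
  me <- me_j[K]
  min(1, min(me * ps / me_j))
}

#' Truncated tail strength statistic
#'
#' \eqn{TS_\tau = K^{-1} \sum_{j: p_{(j)} \le \tau} (1 - p_{(j)} (K+1)/j)}
#' over the ascending order statistics; 0 when no p-value passes the
#' truncation point.
#'
#' @param p vector of SNP-level p-values.
#' @param tau truncation threshold (default 0.05).
#' @return the statistic (larger = stronger signal).
#' @export
tts_stat <- function(p, tau = 0.05) {
  K <- length(p)
  ps <- sort(p)
  j <- which(ps <= tau)
  if (!length(j)) return(0)
  sum(1 - ps[j] * (K + 1) / j) / K
}

#' Truncated product statistic
#'
#' \eqn{W_\tau = \prod_{j: p_j \le \tau} p_j}, defined as 1 for the empty
#' product.
#'
#' @inheritParams tts_stat
#' @return the statistic (smaller = stronger signal).
#' @export
tprod_stat <- function(p, tau = 0.05) {
  sel <- p <= tau
  if (!any(sel)) return(1)
  prod(p[sel])
}

#' Permutation replicates of the SNP-level p-values
#'
#' Permutes the phenotype (rows of `y` only) and recomputes all SNP-level
#' interaction p-values per replicate with the same permutation across
#' SNPs, preserving the LD structure of the tests. These replicates feed
#' the permutation nulls of [ge_tts()] and [ge_tprod()].
#'
#' @inheritParams snp_gxe_pvalues
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return `n_perm` x K matrix of p-values.
#' @export
snp_gxe_perm_pvalues <- function(y, X, z, covariates = NULL, n_perm = 199,
                                 seed = NULL) {
  X <- as.matrix(X)
  N <- length(y)
  C <- if (is.null(covariates)) matrix(0, N, 0) else as.matrix(covariates)
  if (!is.null(seed)) set.seed(seed)
  Y <- vapply(seq_len(n_perm), function(b) y[sample.int(N)], numeric(N))
  .snp_interaction_pvals_cpp(Y, X, as.numeric(z), C)
}

#' Gene-level truncated tail strength test
#'
#' Permutation p-value of [tts_stat()]: the add-one fraction of phenotype-
#' permutation replicates whose statistic is at least the observed one.
#'
#' @param results a [snp_gxe_pvalues()] object.
#' @param null_pvalues matrix of permutation-replicate SNP-level p-values
#'   from [snp_gxe_perm_pvalues()].
#' @param tau truncation threshold.
#' @return gene-level p-value.
#' @export
ge_tts <- function(results, null_pvalues, tau = 0.05) {
  stopifnot(inherits(results, "snp_gxe"))
  obs <- tts_stat(results$p_values, tau)
  null <- apply(null_pvalues, 1L, tts_stat, tau = tau)
  (1 + sum(null >= obs)) / (1 + nrow(null_pvalues))
}

#' Gene-level truncated product test
#'
#' Permutation p-value of [tprod_stat()]: the add-one fraction of
#' replicates whose product statistic is at most the observed one.
#'
#' @inheritParams ge_tts
#' @return gene-level p-value.
#' @export
ge_tprod <- function(results, null_pvalues, tau = 0.05) {
  stopifnot(inherits(results, "snp_gxe"))
  obs <- tprod_stat(results$p_values, tau)
  null <- apply(null_pvalues, 1L, tprod_stat, tau = tau)
  (1 + sum(null <= obs)) / (1 + nrow(null_pvalues))
}

#' All four p-value-combination competitor tests for one gene
#'
#' Computes SNP-level interaction p-values once, then the four gene-level
#' combinations: minimum p (Me-corrected), GATES, truncated tail strength
#' and truncated product. The two truncation tests share one set of
#' phenotype permutations.
#'
#' @inheritParams snp_gxe_pvalues
#' @param tau truncation threshold for the tail-strength and product tests.
#' @param n_perm permutations for their nulls.
#' @param seed RNG seed.
#' @return named numeric vector `c(GE_minP, GE_GATES, GE_tTS, GE_tProd)`.
#' @export
gxe_combine <- function(y, X, z, covariates = NULL, tau = 0.05,
                        n_perm = 199, seed = NULL) {
  res <- snp_gxe_pvalues(y, X, z, covariates)
  nullp <- snp_gxe_perm_pvalues(y, X, z, covariates, n_perm = n_perm,
                                seed = seed)
  c(GE_minP = ge_minp(res),
    GE_GATES = ge_gates(res),
    GE_tTS = ge_tts(res, nullp, tau),
    GE_tProd = ge_tprod(res, nullp, tau))
}
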