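#' Permutation test for the latent interaction coefficient
#'
#' Generates the null distribution of \eqn{|\beta_{12}|} by permutation,
#' re-running the full alternating least-squares fit at the same
#' \eqn{\lambda_S} for every replicate. The empirical p-value uses the
#' add-one estimator \eqn{p = (1 + \#\{|\beta_{12}^*| \ge |\beta_{12}|\}) /
#' (1 + B)}, so ties count against rejection and p-values are never zero.
#'
#' The null hypothesis \eqn{\beta_{12} = 0} is composite: gene and
#' environment main effects may be present. The default
#' `scheme = "freedman-lane"` therefore fits the reduced model without the
#' interaction component (\eqn{y = \beta_1 g + \beta_2 e + \beta_0 + C\beta_p}),
#' permutes its residuals and adds them back onto its fitted values before
#' refitting the full model. Permuting the raw phenotype instead
#' (`scheme = "phenotype"`) destroys the main effects along with the
#' interaction; with a real gene or environment main effect the raw-\eqn{y}
#' null distribution of \eqn{|\beta_{12}^*|} is stochastically larger than
#' the sampling distribution under the composite null, making the test
#' conservative (see the methods vignette). The raw scheme remains exact
#' for the global null of no association at all.
#'
#' \eqn{\lambda_S} is held fixed at the value of the observed fit;
#' cross-validation is not re-run per permutation. Permutations that fail to
#' converge are tallied; if more than 5\% fail the result is flagged.
#'
#' @param object a converged [gxe_fit()] object.
#' @param n_perm number of permutations \eqn{B} (default 5000).
#' @param seed RNG seed making the permutation set reproducible.
#' @param scheme `"freedman-lane"` (default) permutes reduced-model
#'   residuals; `"phenotype"` permutes `y` directly.
#' @return object of class `"gxe_perm"`: `observed_stat`, `null_stats`,
#'   `p_value`, `n_perm`, `seed`, `n_nonconverged`, `flagged`, `scheme`.
#' @examples
#' set.seed(7)
#' X <- matrix(rbinom(150 * 3, 2, 0.3), 150, 3)
#' z <- rnorm(150)
#' fit <- gxe_fit(rnorm(150), X, z, lambda = 0.1)
#' gxe_perm_test(fit, n_perm = 99, seed = 1)$p_value
#' @export
gxe_perm_test <- function(object, n_perm = 5000, seed = NULL,
                          scheme = c("freedman-lane", "phenotype")) {
  stopifnot(inherits(object, "gxe_fit"))
  scheme <- match.arg(scheme)
  if (n_perm < 1) stop("n_perm must be >= 1")
  N <- object$N
  d <- object$data

  if (scheme == "freedman-lane") {
    red_fit <- .reduced_fitted_cpp(d$y, d$X, d$e, d$C, object$lambda,
                                   object$penalize_b, object$w0[, 1],
                                   object$tol, object$max_iter)
    offset <- as.numeric(red_fit)
    # rescale the reduced-model residuals for the degrees of freedom the
    # reduced fit consumed (K weight directions + environment + intercept +
    # covariates); without this the permuted errors are under-dispersed and
    # small-sample p-values shift low
    df_red <- min(N - 2, object$K + 2 + ncol(d$C))
    part <- (d$y - offset) * sqrt(N / (N - df_red))
  } else {
    offset <- numeric(N)
    part <- d$y
  }

  if (!is.null(seed)) set.seed(seed)
  perm <- t(vapply(seq_len(n_perm), function(i) sample.int(N), integer(N)))

  # every replicate fit runs the same deterministic map: ALS started at the
  # observed solution's weights (for the observed phenotype this map
  # returns the observed fit itself, so the statistic is computed
  # symmetrically across the identity and all permutations)
  w_start <- matrix(object$w_internal, ncol = 1)
  res <- .perm_beta12_cpp(offset, part, d$X, d$e, d$C, object$lambda,
                          object$penalize_b, w_start, object$tol,
                          object$max_iter, perm - 1L)
  null_stats <- as.numeric(res$stat)
  conv <- as.numeric(res$converged)

  n_bad <- sum(conv == 0 | !is.finite(null_stats))
  flagged <- n_bad > 0.05 * n_perm
  if (n_bad > 0)
    message("gxe_perm_test: ", n_bad, " of ", n_perm,
            " permutation fits did not converge",
            if (flagged) " (FLAGGED: >5%)" else "")

  observed <- abs(object$coefficients[["interaction"]])
  ok <- is.finite(null_stats)
  p <- (1 + sum(null_stats[ok] >= observed)) / (1 + n_perm)

  structure(list(observed_stat = observed, null_stats = null_stats,
                 p_value = p, n_perm = n_perm, seed = seed,
                 n_nonconverged = n_bad, flagged = flagged,
                 scheme = scheme),
            class = "gxe_perm")
}

#' Bonferroni significance threshold for a gene-based scan
#'
#' @param alpha family-wise significance level.
#' @param n_genes number of genes tested.
#' @return `alpha / n_genes`. For a 16,361-gene genome-wide scan at
#'   `alpha = 0.05` this is 3.06e-6.
#' @examples
#' bonferroni_threshold(0.05, 16361)
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_genes) {
  stopifnot(length(n_genes) == 1, n_genes >= 1, alpha > 0, alpha <= 1)
  alpha / n_genes
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR-adjusted p-values (q-values) with enforced monotonicity,
#' returned in the input order.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return vector of q-values, same length and order as the input.
#' @examples
#' bh_qvalues(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_qvalues <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  stats::p.adjust(p_values, method = "BH")
}
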