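#' Method adaptors for the simulation harnesses
#'
#' The experiment harnesses are method-agnostic: any function
#' `function(data, seed)` mapping a simulated dataset (list with `y`,
#' `genotypes` or `X`, `z`, optional `covariates`) to a single p-value can
#' be plugged in. These factories wrap the package's tests in that shape.
#'
#' `latent_method()` runs the latent-component ridge fit (cross-validated
#' \eqn{\lambda_S} by default) followed by the phenotype-permutation test of
#' the interaction coefficient. `minp_method()`, `gates_method()`,
#' `tts_method()` and `tprod_method()` run the SNP-level interaction scans
#' and the corresponding p-value combination.
#'
#' @param n_perm permutations for the permutation-based tests.
#' @param lambda fixed ridge penalty; `NULL` cross-validates per dataset.
#' @param folds CV folds when `lambda` is `NULL`.
#' @param tau truncation threshold for the truncation-based combiners.
#' @return a `function(data, seed)` returning a p-value.
#' @name method_adaptors
NULL

dataset_parts <- function(data) {
  X <- if (!is.null(data$genotypes)) data$genotypes$values else data$X
  list(y = data$y, X = X, z = data$z, C = data$covariates)
}

#' @rdname method_adaptors
#' @export
latent_method <- function(n_perm = 199, lambda = NULL, folds = 5) {
  function(data, seed = NULL) {
    d <- dataset_parts(data)
    fit <- gxe_fit(d$y, d$X, d$z, covariates = d$C, lambda = lambda,
                   folds = folds, seed = seed)
    gxe_perm_test(fit, n_perm = n_perm, seed = seed)$p_value
  }
}

#' @rdname method_adaptors
#' @export
minp_method <- function() {
  function(data, seed = NULL) {
    d <- dataset_parts(data)
    ge_minp(snp_gxe_pvalues(d$y, d$X, d$z, d$C))
  }
}

#' @rdname method_adaptors
#' @export
gates_method <- function() {
  function(data, seed = NULL) {
    d <- dataset_parts(data)
    ge_gates(snp_gxe_pvalues(d$y, d$X, d$z, d$C))
  }
}

#' @rdname method_adaptors
#' @export
tts_method <- function(n_perm = 199, tau = 0.05) {
  function(data, seed = NULL) {
    d <- dataset_parts(data)
    res <- snp_gxe_pvalues(d$y, d$X, d$z, d$C)
    nullp <- snp_gxe_perm_pvalues(d$y, d$X, d$z, d$C, n_perm = n_perm,
                                  seed = seed)
    ge_tts(res, nullp, tau)
  }
}

#' @rdname method_adaptors
#' @export
tprod_method <- function(n_perm = 199, tau = 0.05) {
  function(data, seed = NULL) {
    d <- dataset_parts(data)
    res <- snp_gxe_pvalues(d$y, d$X, d$z, d$C)
    nullp <- snp_gxe_perm_pvalues(d$y, d$X, d$z, d$C, n_perm = n_perm,
                                  seed = seed)
    ge_tprod(res, nullp, tau)
  }
}

# shared dataset loop: per-dataset seeds derived from the master seed so
# results do not depend on evaluation order
run_datasets <- function(config, n_datasets, methods, seed) {
  set.seed(seed)
  data_seeds <- sample.int(2147483646L, n_datasets)
  method_seeds <- sample.int(2147483646L, n_datasets)
  p <- matrix(NA_real_, n_datasets, length(methods),
              dimnames = list(NULL, names(methods)))
  for (i in seq_len(n_datasets)) {
    cfg <- config
    cfg$seed <- data_seeds[i]
    data <- simulate_gxe_dataset(cfg)
    for (m in seq_along(methods))
      p[i, m] <- methods[[m]](data, seed = method_seeds[i])
  }
  p
}

#' Empirical type-I-error experiment
#'
#' Generates `n_datasets` null datasets (the config must have
#' `beta12 = 0`), applies a method to each, and reports the fraction of
#' p-values at or below each significance level together with exact
#' (Clopper-Pearson) binomial 95\% confidence intervals.
#'
#' @param config a [sim_config()] with `beta12 = 0`.
#' @param n_datasets number of replicate datasets (1000 in a full-scale
#'   run).
#' @param alpha_levels nominal significance levels.
#' @param method a `function(data, seed)` p-value callable, e.g.
#'   [latent_method()].
#' @param seed master seed; per-dataset seeds are derived from it.
#' @return data frame with one row per level: `alpha`, `rejections`,
#'   `rate`, `ci_lo`, `ci_hi`, `n_datasets`.
#' @export
type1_experiment <- function(config, n_datasets = 1000,
                             alpha_levels = c(0.05, 0.01, 0.005),
                             method = latent_method(), seed = 1) {
  stopifnot(inherits(config, "gxe_sim_config"))
  if (config$beta12 != 0)
    stop("type-I-error experiment requires beta12 = 0 in the config")
  p <- run_datasets(config, n_datasets, list(method = method), seed)[, 1]
  out <- do.call(rbind, lapply(alpha_levels, function(a) {
    x <- sum(p <= a)
    ci <- exact_binom_ci(x, n_datasets)
    data.frame(alpha = a, rejections = x, rate = x / n_datasets,
               ci_lo = ci[1], ci_hi = ci[2], n_datasets = n_datasets)
  }))
  attr(out, "p_values") <- p
  out
}

#' Empirical power experiment
#'
#' For each interaction effect size in `beta12_grid` and each method,
#' generates `n_datasets` datasets and reports the rejection fraction at
#' level `alpha` with exact binomial 95\% confidence intervals. All methods
#' see the same datasets at each grid point.
#'
#' @param config a [sim_config()]; its `beta12` is overridden by the grid.
#' @param beta12_grid interaction effect sizes (e.g. `seq(0.5, 0.9, 0.1)`
#'   for a 5-SNP gene or `seq(0.1, 0.5, 0.1)` for a 20-SNP gene).
#' @param n_datasets replicate datasets per grid point.
#' @param alpha significance level.
#' @param methods named list of `function(data, seed)` callables.
#' @param seed master seed.
#' @return data frame with columns `method`, `beta12`, `rejections`,
#'   `power`, `ci_lo`, `ci_hi`, `n_datasets`.
#' @export
power_experiment <- function(config, beta12_grid = seq(0.5, 0.9, 0.1),
                             n_datasets = 1000, alpha = 0.05,
                             methods = list(latent = latent_method()),
                             seed = 1) {
  stopifnot(inherits(config, "gxe_sim_config"), length(methods) >= 1)
  if (is.null(names(methods)))
    names(methods) <- paste0("method", seq_along(methods))
  rows <- list()
  for (b in beta12_grid) {
    cfg <- config
    cfg$beta12 <- b
    p <- run_datasets(cfg, n_datasets, methods,
                      seed = seed + round(1000 * b))
    for (m in names(methods)) {
      x <- sum(p[, m] <= alpha)
      ci <- exact_binom_ci(x, n_datasets)
      rows[[length(rows) + 1L]] <-
        data.frame(method = m, beta12 = b, rejections = x,
                   power = x / n_datasets, ci_lo = ci[1], ci_hi = ci[2],
                   n_datasets = n_datasets)
    }
  }
  do.call(rbind, rows)
}
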