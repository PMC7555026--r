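#' Genome-wide gene-based G\eqn{\times}E scan
#'
#' End-to-end driver: QC-filter the genotypes, map SNPs to genes with
#' flanking windows, then per gene select \eqn{\lambda_S} by
#' cross-validation (unless fixed), fit the latent-component model and run
#' the phenotype-permutation interaction test. Benjamini-Hochberg q-values
#' are computed across all tested genes and the Bonferroni threshold is
#' reported in the log.
#'
#' Per-gene RNG streams are derived deterministically from
#' `(seed, gene_id)`, so results are reproducible and independent of gene
#' processing order.
#'
#' @param genotypes a [genotype_matrix()] (variants need `chrom`/`pos` for
#'   mapping).
#' @param pheno data frame holding phenotype, environment and covariates;
#'   rows must align with `genotypes$samples` (a `sample` column, when
#'   present, is checked against them).
#' @param genes gene annotation data frame ([read_gene_annotation()]).
#' @param y_col,z_col column names in `pheno` of the phenotype and
#'   environment.
#' @param covariate_cols optional character vector of covariate columns.
#' @param flank SNP-to-gene flanking window in bp.
#' @param maf_min,miss_max,hwe_min QC thresholds, see [apply_qc()].
#' @param lambda fixed ridge penalty; `NULL` cross-validates per gene.
#' @param lambda_grid,folds cross-validation settings.
#' @param n_perm permutations per gene (5000 for a full-scale scan).
#' @param alpha significance level used for the reported Bonferroni
#'   threshold.
#' @param seed master seed.
#' @param competitors if `TRUE`, append the four p-value-combination tests
#'   per gene.
#' @param tau truncation threshold for the truncation-based competitors.
#' @return data frame of class `"gxe_scan"` with one row per gene kept:
#'   `gene_id`, `chrom`, `start`, `end`, `n_snps`, `lambda_s`, `beta1`,
#'   `beta2`, `beta12`, `p_perm`, `q_value` and, optionally, the
#'   competitor columns.
#' @export
gxe_scan <- function(genotypes, pheno, genes, y_col, z_col,
                     covariate_cols = NULL, flank = 20000,
                     maf_min = 0.01, miss_max = 0.05, hwe_min = 1e-6,
                     lambda = NULL, lambda_grid = seq(0, 0.5, length.out = 15),
                     folds = 5, n_perm = 5000, alpha = 0.05, seed = 1,
                     competitors = FALSE, tau = 0.05) {
  stopifnot(inherits(genotypes, "genotype_matrix"), is.data.frame(pheno))
  for (col in c(y_col, z_col, covariate_cols))
    if (!col %in% names(pheno)) stop("column not in pheno table: ", col)
  if (nrow(pheno) != length(genotypes$samples))
    stop("pheno rows (", nrow(pheno), ") do not match genotype samples (",
         length(genotypes$samples), ")")
  if ("sample" %in% names(pheno)) {
    bad <- which(as.character(pheno$sample) != genotypes$samples)
    if (length(bad))
      stop("sample-ID mismatch between pheno and genotypes at rows: ",
           paste(utils::head(bad, 10), collapse = ", "))
  }
  ph <- pheno[c(y_col, z_col, covariate_cols)]
  if (anyNA(ph)) stop("missing values in phenotype/environment/covariates")

  G <- apply_qc(genotypes, maf_min = maf_min, miss_max = miss_max,
                hwe_min = hwe_min)
  sets <- map_snps_to_genes(G$variants, genes, flank = flank)
  message("gxe_scan: ", length(sets), " gene(s) with >= 1 post-QC SNP; ",
          "Bonferroni threshold at alpha = ", alpha, ": ",
          format(bonferroni_threshold(alpha, max(1, length(sets))),
                 digits = 3))
  message("gxe_scan: minimum attainable permutation p-value = ",
          format(1 / (n_perm + 1), digits = 3), " at ", n_perm,
          " permutations")

  y <- ph[[y_col]]
  z <- ph[[z_col]]
  C <- if (length(covariate_cols)) as.matrix(ph[covariate_cols]) else NULL

  if (!length(sets)) {
    warning("no genes contained SNPs after QC and mapping; empty result")
    empty <- data.frame(gene_id = character(0), chrom = character(0),
                        start = integer(0), end = integer(0),
                        n_snps = integer(0), lambda_s = numeric(0),
                        beta1 = numeric(0), beta2 = numeric(0),
                        beta12 = numeric(0), p_perm = numeric(0),
                        q_value = numeric(0))
    class(empty) <- c("gxe_scan", class(empty))
    return(empty)
  }

  rows <- lapply(sets, function(gs) {
    gseed <- derive_seed(seed, gs$gene_id)
    X <- G$values[, gs$snp_indices, drop = FALSE]
    fit <- gxe_fit(y, X, z, covariates = C, lambda = lambda,
                   lambda_grid = lambda_grid, folds = folds, seed = gseed)
    pt <- gxe_perm_test(fit, n_perm = n_perm, seed = gseed)
    row <- data.frame(gene_id = gs$gene_id, chrom = gs$chrom,
                      start = gs$start, end = gs$end,
                      n_snps = length(gs$snp_indices),
                      lambda_s = fit$lambda,
                      beta1 = fit$coefficients[["gene"]],
                      beta2 = fit$coefficients[["env"]],
                      beta12 = fit$coefficients[["interaction"]],
                      p_perm = pt$p_value)
    if (competitors) {
      cp <- gxe_combine(y, X, z, covariates = C, tau = tau,
                        n_perm = n_perm, seed = gseed)
      row <- cbind(row, as.data.frame(as.list(cp)))
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q_value <- bh_qvalues(out$p_perm)
  if (competitors)
    out <- out[c(setdiff(names(out), c("GE_minP", "GE_GATES", "GE_tTS",
                                       "GE_tProd")),
                 c("GE_minP", "GE_GATES", "GE_tTS", "GE_tProd"))]
  class(out) <- c("gxe_scan", class(out))
  out
}

#' Write scan results as TSV
#'
#' @param results a [gxe_scan()] data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gxe_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
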