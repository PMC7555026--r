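#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact two-sided test of HWE from genotype counts, by full enumeration of
#' the conditional distribution of the heterozygote count given the allele
#' counts (the SNP-exact test of Wigginton-style enumeration, in log space).
#' The p-value is the total probability of heterozygote counts no more
#' likely than the observed one.
#'
#' @param n_aa count of minor-allele homozygotes.
#' @param n_ab count of heterozygotes.
#' @param n_bb count of major-allele homozygotes.
#' @return exact p-value in (0, 1].
#' @examples
#' hwe_exact_test(9, 42, 49)   # near HWE for MAF 0.3, n = 100
#' hwe_exact_test(0, 100, 0)   # all heterozygotes: strong departure
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  na <- 2 * n_aa + n_ab          # minor allele count
  if (na > n) {                  # ensure 'a' is the minor allele
    tmp <- n_aa; n_aa <- n_bb; n_bb <- tmp
    na <- 2 * n_aa + n_ab
  }
  if (na == 0) return(1)
  # heterozygote counts share the parity of the minor allele count
  h <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  aa <- (na - h) / 2
  bb <- n - aa - h
  logp <- h * log(2) + lfactorial(n) -
    (lfactorial(aa) + lfactorial(h) + lfactorial(bb)) +
    lfactorial(na) + lfactorial(2 * n - na) - lfactorial(2 * n)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[h == n_ab]
  sum(p[p <= obs * (1 + 1e-9)])
}

#' Genotype quality-control filters
#'
#' Removes variants with minor allele frequency at or below `maf_min`,
#' missing fraction above `miss_max`, or exact Hardy-Weinberg p-value at or
#' below `hwe_min` (the thresholds of a standard common-variant GWAS QC:
#' MAF > 0.01, missingness <= 5\%, HWE p > 1e-6). Remaining missing
#' genotypes in the surviving columns are mean-imputed per column, which
#' preserves each column's observed mean exactly. The HWE and MAF filters
#' use only entries with whole-number codes 0/1/2, so a second application
#' to an already-imputed matrix is a no-op (idempotence).
#'
#' @param G a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency (exclusive bound).
#' @param miss_max maximum missing fraction (inclusive bound).
#' @param hwe_min minimum HWE exact p-value (exclusive bound).
#' @return the column-filtered, mean-imputed [genotype_matrix()]; filter
#'   counts are attached as attribute `"qc_log"` and reported via
#'   `message()`.
#' @export
apply_qc <- function(G, maf_min = 0.01, miss_max = 0.05, hwe_min = 1e-6) {
  stopifnot(inherits(G, "genotype_matrix"))
  V <- G$values
  miss <- colMeans(is.na(V))
  af <- colMeans(V, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  hwe <- vapply(seq_len(ncol(V)), function(k) {
    v <- V[, k]
    v <- v[!is.na(v) & v %in% c(0, 1, 2)]
    af_k <- mean(v) / 2
    minor_is_alt <- af_k <= 0.5
    n2 <- sum(v == 2); n1 <- sum(v == 1); n0 <- sum(v == 0)
    if (minor_is_alt) hwe_exact_test(n2, n1, n0) else hwe_exact_test(n0, n1, n2)
  }, numeric(1))

  keep <- maf > maf_min & miss <= miss_max & hwe > hwe_min
  keep[is.na(keep)] <- FALSE   # e.g. an all-missing column
  log <- c(input = ncol(V), fail_maf = sum(maf <= maf_min),
           fail_miss = sum(miss > miss_max),
           fail_hwe = sum(hwe <= hwe_min), kept = sum(keep))
  message("apply_qc: kept ", log[["kept"]], "/", log[["input"]],
          " variants (MAF fail ", log[["fail_maf"]],
          ", missingness fail ", log[["fail_miss"]],
          ", HWE fail ", log[["fail_hwe"]], ")")
  if (!any(keep))
    stop("apply_qc removed every variant; nothing left to analyze")

  V <- V[, keep, drop = FALSE]
  for (k in seq_len(ncol(V))) {
    nas <- is.na(V[, k])
    if (any(nas)) V[nas, k] <- mean(V[!nas, k])
  }
  out <- genotype_matrix(V, variants = G$variants[keep, , drop = FALSE],
                         samples = G$samples, validate = FALSE)
  attr(out, "qc_log") <- log
  out
}
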