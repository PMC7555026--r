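#' Genotype matrix container
#'
#' A light container for an N x K additive-coded genotype matrix: `values`
#' holds allele counts in \{0, 1, 2\} (NA for missing; fractional dosages
#' appear only after mean imputation by [apply_qc()]), `variants` is a data
#' frame with columns `chrom`, `pos` (1-based bp) and `id`, and `samples`
#' the ordered sample ids.
#'
#' @param values numeric matrix of allele counts.
#' @param variants data frame with one row per column of `values`.
#' @param samples character vector of row ids.
#' @param validate check the \{0,1,2,NA\} coding (disable for imputed
#'   dosages).
#' @return object of class `"genotype_matrix"`.
#' @export
genotype_matrix <- function(values, variants = NULL, samples = NULL,
                            validate = TRUE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(samples))
    samples <- rownames(values) %||% paste0("sample", seq_len(nrow(values)))
  if (is.null(variants))
    variants <- data.frame(
      chrom = NA_character_, pos = NA_integer_,
      id = colnames(values) %||% paste0("snp", seq_len(ncol(values))))
  stopifnot(nrow(variants) == ncol(values), length(samples) == nrow(values),
            all(c("chrom", "pos", "id") %in% names(variants)))
  if (validate) {
    v <- values[!is.na(values)]
    if (length(v) && !all(v %in% c(0, 1, 2)))
      stop("non-missing genotype entries must be 0, 1 or 2")
  }
  rownames(values) <- samples
  colnames(values) <- variants$id
  structure(list(values = values, variants = variants, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$samples), "samples x",
      nrow(x$variants), "variants\n")
  cat("  missing:", sum(is.na(x$values)), "entries\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

#' Read genotypes from VCF, PLINK binary or dosage TSV
#'
#' Additive coding counts the non-reference (alternate) allele for VCF, the
#' A1 allele for PLINK, and takes dosage-table entries verbatim. Sample
#' order is preserved from the file. Non-biallelic VCF records are skipped
#' with a warning.
#'
#' @param path file path. For `format = "plink-bed"` either the `.bed` file
#'   or the fileset prefix (the matching `.bim`/`.fam` must sit alongside).
#' @param format one of `"dosage-tsv"` (tab-separated, header row of variant
#'   ids, first column sample ids), `"vcf"`, `"plink-bed"`.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("dosage-tsv", "vcf", "plink-bed")) {
  format <- match.arg(format)
  switch(format,
         "dosage-tsv" = read_dosage_tsv(path),
         "vcf" = read_vcf_genotypes(path),
         "plink-bed" = read_plink_bed(path))
}

read_dosage_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) stop("malformed dosage table '", path, "': ",
                             conditionMessage(e)))
  if (ncol(tab) < 2) stop("dosage table needs a sample column plus variants")
  samples <- as.character(tab[[1]])
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(tab[-1], is.numeric, logical(1)))[1]
    stop("non-numeric dosage column: ", names(tab)[-1][bad])
  }
  genotype_matrix(vals,
                  variants = data.frame(chrom = NA_character_,
                                        pos = NA_integer_,
                                        id = colnames(vals)),
                  samples = samples)
}

#' Write a genotype matrix as a dosage TSV
#'
#' Inverse of `read_genotypes(..., format = "dosage-tsv")`.
#' @param G a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dosage <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  tab <- data.frame(sample = G$samples, G$values, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_vcf_genotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  biallelic <- !grepl(",", alt) & !is.na(alt) & !is.na(ref)
  if (any(!biallelic))
    warning("skipping ", sum(!biallelic), " non-biallelic variant(s)")
  if (!any(biallelic)) stop("no biallelic variants in ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  count_alt <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_real_)
    sum(alleles != "0")
  }
  vals <- matrix(vapply(gt, count_alt, numeric(1)),
                 nrow = nrow(gt), ncol = ncol(gt))
  vals <- t(vals)  # rows = samples, cols = variants
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[
    is.na(ids) | ids == "."]
  genotype_matrix(vals,
                  variants = data.frame(chrom = as.character(fix[, "CHROM"]),
                                        pos = as.integer(fix[, "POS"]),
                                        id = ids),
                  samples = colnames(gt))
}

# PLINK 1 binary fileset (.bed/.bim/.fam), SNP-major. Two-bit codes per the
# format spec: 00 = two A1 alleles, 10 = heterozygote, 11 = zero A1 alleles,
# 01 = missing. Additive coding counts A1 (conventionally the minor allele).
read_plink_bed <- function(path) {
  prefix <- sub("\\.bed$", "", path)
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("file not found: ", f)
  bim_tab <- utils::read.table(bim, stringsAsFactors = FALSE,
                               col.names = c("chrom", "id", "cm", "pos",
                                             "a1", "a2"))
  fam_tab <- utils::read.table(fam, stringsAsFactors = FALSE)
  N <- nrow(fam_tab)
  K <- nrow(bim_tab)
  raw <- readBin(bed, "raw", n = file.info(bed)$size)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file (bad magic): ", bed)
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major .bed files are supported")
  bpv <- ceiling(N / 4)
  if (length(raw) - 3 < bpv * K)
    stop("truncated .bed file: ", bed)
  body <- raw[-(1:3)]
  lut <- c(`0` = 2, `1` = NA_real_, `2` = 1, `3` = 0)  # two-bit code -> dose
  vals <- matrix(NA_real_, N, K)
  idx <- as.integer(body)
  codes <- cbind(bitwAnd(idx, 3L), bitwAnd(bitwShiftR(idx, 2L), 3L),
                 bitwAnd(bitwShiftR(idx, 4L), 3L),
                 bitwAnd(bitwShiftR(idx, 6L), 3L))
  for (k in seq_len(K)) {
    block <- codes[((k - 1) * bpv + 1):(k * bpv), , drop = FALSE]
    vals[, k] <- lut[as.character(t(block))][seq_len(N)]
  }
  genotype_matrix(vals,
                  variants = data.frame(chrom = as.character(bim_tab$chrom),
                                        pos = as.integer(bim_tab$pos),
                                        id = bim_tab$id),
                  samples = as.character(fam_tab[[2]]))
}
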