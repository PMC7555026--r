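#' Read gene annotation intervals
#'
#' BED4 input (0-based half-open) is converted to the package's internal
#' 1-based inclusive coordinates on read; `"tsv"` input is a header-ed
#' tab-separated table with 1-based inclusive columns
#' `gene_id, chrom, start, end`.
#'
#' @param path annotation file.
#' @param format `"bed"` (chrom, start, end, name; no header) or `"tsv"`.
#' @return data frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @export
read_gene_annotation <- function(path, format = c("bed", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "bed") {
    tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    if (ncol(tab) < 4) stop("BED4 needs chrom, start, end, name")
    data.frame(gene_id = as.character(tab[[4]]),
               chrom = as.character(tab[[1]]),
               start = as.integer(tab[[2]]) + 1L,  # 0-based -> 1-based
               end = as.integer(tab[[3]]),
               stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "start", "end")
    if (!all(need %in% names(tab)))
      stop("TSV annotation needs columns: ", paste(need, collapse = ", "))
    tab[need]
  }
}

#' Assign SNPs to genes with flanking windows
#'
#' A SNP belongs to a gene when it lies on the same chromosome and within
#' the gene interval expanded by `flank` base pairs on both sides,
#' boundaries inclusive: \eqn{start - flank \le pos \le end + flank}. A SNP
#' may belong to several overlapping genes; genes that collect no SNPs are
#' omitted.
#'
#' @param variants data frame with columns `chrom`, `pos` (1-based), `id` —
#'   e.g. the `variants` slot of a [genotype_matrix()].
#' @param genes data frame as returned by [read_gene_annotation()].
#' @param flank flanking window in bp (default 20 kb, the usual
#'   gene-body +/- 20 kb convention).
#' @return named list of `"gene_set"` objects, each with `gene_id`,
#'   `chrom`, `start`, `end` and `snp_indices` (strictly increasing column
#'   indices into the genotype matrix).
#' @export
map_snps_to_genes <- function(variants, genes, flank = 20000) {
  stopifnot(all(c("chrom", "pos", "id") %in% names(variants)),
            all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  if (nrow(variants) == 0 || nrow(genes) == 0) return(list())
  mappable <- which(!is.na(variants$chrom) & !is.na(variants$pos))
  if (!length(mappable)) {
    message("map_snps_to_genes: no variants carry chrom/pos coordinates")
    return(list())
  }
  variants <- variants[mappable, , drop = FALSE]
  snp_gr <- GenomicRanges::GRanges(
    seqnames = as.character(variants$chrom),
    ranges = IRanges::IRanges(start = variants$pos, width = 1))
  gene_gr <- GenomicRanges::GRanges(
    seqnames = as.character(genes$chrom),
    ranges = IRanges::IRanges(start = pmax(1L, genes$start - flank),
                              end = genes$end + flank))
  # (disjoint chromosome sets between SNPs and genes are fine: no overlap)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(snp_gr, gene_gr))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  out <- lapply(sort(unique(sh)), function(gidx) {
    structure(list(gene_id = genes$gene_id[gidx],
                   chrom = as.character(genes$chrom[gidx]),
                   start = genes$start[gidx],
                   end = genes$end[gidx],
                   snp_indices = sort(mappable[qh[sh == gidx]])),
              class = "gene_set")
  })
  names(out) <- vapply(out, `[[`, character(1), "gene_id")
  out
}
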