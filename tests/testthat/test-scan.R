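make_toy_scan <- function(seed = 60, n_perm = 199, beta12 = 0.9, N = 300) {
  set.seed(seed)
  # three 5-SNP genes laid out on one chromosome, far enough apart that
  # flanking windows do not overlap
  blocks <- lapply(1:3, function(b)
    simulate_genotypes(N, 5, maf = runif(5, 0.1, 0.4), ld_rho = 0.5))
  vals <- do.call(cbind, lapply(blocks, function(b) b$values))
  pos <- as.integer(c(1e5 + 1000 * (1:5), 5e5 + 1000 * (1:5),
                      9e5 + 1000 * (1:5)))
  G <- genotype_matrix(vals,
                       variants = data.frame(chrom = "1", pos = pos,
                                             id = paste0("snp", 1:15)),
                       samples = paste0("s", seq_len(N)))
  genes <- data.frame(gene_id = c("geneA", "geneB", "geneC"), chrom = "1",
                      start = c(1e5L, 5e5L, 9e5L),
                      end = c(1.1e5L, 5.1e5L, 9.1e5L))
  # interaction signal in geneB only
  cfg <- sim_config(N = N, K = 5, beta12 = beta12)
  ph <- simulate_phenotype(blocks[[2]], cfg)
  pheno <- data.frame(sample = paste0("s", seq_len(N)), sbp = ph$y,
                      alcohol = ph$z)
  list(G = G, genes = genes, pheno = pheno)
}

test_that("the causal gene attains the smallest permutation p-value", {
  toy <- make_toy_scan()
  res <- suppressMessages(
    gxe_scan(toy$G, toy$pheno, toy$genes, y_col = "sbp", z_col = "alcohol",
             n_perm = 199, seed = 1))
  expect_s3_class(res, "gxe_scan")
  expect_equal(nrow(res), 3)
  expect_equal(res$n_snps, rep(5L, 3))
  expect_equal(res$gene_id[which.min(res$p_perm)], "geneB")
  expect_lt(res$p_perm[res$gene_id == "geneB"], 0.05)
  expect_equal(res$q_value, bh_qvalues(res$p_perm))
})

test_that("scan output is byte-identical across reruns with one seed", {
  toy <- make_toy_scan(seed = 61, beta12 = 0)
  r1 <- suppressMessages(
    gxe_scan(toy$G, toy$pheno, toy$genes, y_col = "sbp", z_col = "alcohol",
             n_perm = 49, seed = 9))
  r2 <- suppressMessages(
    gxe_scan(toy$G, toy$pheno, toy$genes, y_col = "sbp", z_col = "alcohol",
             n_perm = 49, seed = 9))
  expect_identical(r1, r2)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_gxe_results(r1, p1)
  write_gxe_results(r2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("the log reports the minimum attainable p-value", {
  toy <- make_toy_scan(seed = 62, beta12 = 0, N = 100)
  msgs <- capture.output(
    res <- gxe_scan(toy$G, toy$pheno, toy$genes, y_col = "sbp",
                    z_col = "alcohol", n_perm = 19, seed = 1),
    type = "message")
  expect_true(any(grepl("0.05", msgs)))
  expect_true(any(grepl("Bonferroni", msgs)))
})

test_that("a scan with zero mapped genes returns an empty result", {
  toy <- make_toy_scan(seed = 63, beta12 = 0, N = 100)
  far_genes <- data.frame(gene_id = "nowhere", chrom = "7",
                          start = 1L, end = 10L)
  expect_warning(
    res <- suppressMessages(
      gxe_scan(toy$G, toy$pheno, far_genes, y_col = "sbp",
               z_col = "alcohol", n_perm = 19, seed = 1)),
    "no genes")
  expect_equal(nrow(res), 0)
})

test_that("sample-ID mismatches are a hard error naming offenders", {
  toy <- make_toy_scan(seed = 64, beta12 = 0, N = 100)
  toy$pheno$sample[3] <- "intruder"
  expect_error(
    gxe_scan(toy$G, toy$pheno, toy$genes, y_col = "sbp", z_col = "alcohol"),
    "mismatch.*3")
})

test_that("competitor columns are appended when requested", {
  toy <- make_toy_scan(seed = 65, beta12 = 0, N = 120)
  res <- suppressMessages(
    gxe_scan(toy$G, toy$pheno, toy$genes, y_col = "sbp", z_col = "alcohol",
             n_perm = 49, seed = 2, competitors = TRUE))
  expect_true(all(c("GE_minP", "GE_GATES", "GE_tTS", "GE_tProd") %in%
                    names(res)))
})

test_that("the command-line driver runs scan and simulate end to end", {
  skip_on_os("windows")
  cli <- system.file("cli", "gxescan.R", package = "gxescan")
  skip_if(cli == "", "cli script not installed")
  dir <- withr::local_tempdir()
  toy <- make_toy_scan(seed = 66, beta12 = 0.9, N = 150)
  geno_path <- file.path(dir, "geno.tsv")
  write_dosage(toy$G, geno_path)
  pheno_path <- file.path(dir, "pheno.tsv")
  write.table(toy$pheno, pheno_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  genes_path <- file.path(dir, "genes.tsv")
  write.table(data.frame(gene_id = c("geneA", "geneB", "geneC"),
                         chrom = "1",
                         start = c(1e5L, 5e5L, 9e5L),
                         end = c(1.1e5L, 5.1e5L, 9.1e5L)),
              genes_path, sep = "\t", quote = FALSE, row.names = FALSE)
  out_path <- file.path(dir, "res.tsv")
  status <- system2("Rscript",
                    c(cli, "scan", "--genotypes", geno_path,
                      "--pheno", pheno_path, "--y", "sbp", "--z", "alcohol",
                      "--genes", genes_path, "--genes-format", "tsv",
                      "--n-perm", "19", "--out", out_path),
                    stdout = FALSE, stderr = FALSE)
  # dosage input has no chrom/pos: mapping yields no genes -> still exit 0
  expect_equal(status, 0L)
  sim_out <- file.path(dir, "sim.tsv")
  status2 <- system2("Rscript",
                     c(cli, "simulate", "--experiment", "type1",
                       "--n-datasets", "5", "--n-perm", "19", "--N", "60",
                       "--K", "2", "--out", sim_out),
                     stdout = FALSE, stderr = FALSE)
  expect_equal(status2, 0L)
  tab <- read.table(sim_out, header = TRUE, sep = "\t", comment.char = "#")
  expect_equal(nrow(tab), 3)
  status3 <- system2("Rscript", c(cli, "simulate", "--experiment", "bogus",
                                  "--out", sim_out),
                     stdout = FALSE, stderr = FALSE)
  expect_equal(status3, 1L)
})
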