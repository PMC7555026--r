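snp_res <- function(p, corr) structure(list(p_values = p, genotype_corr = corr),
                                       class = "snp_gxe")

test_that("single-SNP interaction regression matches the closed-form t-test", {
  set.seed(40)
  N <- 500
  x <- rbinom(N, 2, 0.3)
  z <- rnorm(N)
  y <- 0.2 * x + 0.1 * z + 1.0 * x * z + rnorm(N)
  p <- snp_gxe_test(y, x, z)
  expect_lt(p, 1e-6)
  # oracle: lm t-test for the product coefficient
  ols <- summary(lm(y ~ x + z + I(x * z)))
  expect_equal(p, ols$coefficients["I(x * z)", 4], tolerance = 1e-10)
  # with a covariate
  C <- cbind(rnorm(N))
  p2 <- snp_gxe_test(y, x, z, covariates = C)
  ols2 <- summary(lm(y ~ x + z + I(x * z) + C))
  expect_equal(p2, ols2$coefficients["I(x * z)", 4], tolerance = 1e-10)
})

test_that("constant SNP gives p = 1 with a warning", {
  set.seed(41)
  expect_warning(p <- snp_gxe_test(rnorm(50), rep(2, 50), rnorm(50)),
                 "collinear")
  expect_equal(p, 1)
})

test_that("SNP-level test is calibrated under the null", {
  set.seed(42)
  rej <- vapply(1:1000, function(i) {
    x <- rbinom(120, 2, 0.3)
    snp_gxe_test(rnorm(120), x, rnorm(120)) <= 0.05
  }, logical(1))
  ci <- qbinom(c(0.005, 0.995), 1000, 0.05) / 1000
  expect_gte(mean(rej), ci[1])
  expect_lte(mean(rej), ci[2])
})

test_that("effective number of tests: independence and redundancy limits", {
  expect_equal(effective_tests(diag(5)), 5)
  expect_equal(effective_tests(matrix(1, 4, 4)), 1)
  expect_equal(effective_tests(matrix(1, 1, 1)), 1)
})

test_that("minP reduces correctly in the independence and redundancy limits", {
  expect_equal(ge_minp(snp_res(0.2, matrix(1, 1, 1))), 0.2)
  p <- c(0.01, 0.3, 0.5, 0.7, 0.9)
  expect_equal(ge_minp(snp_res(p, diag(5))), 1 - 0.99^5)
  expect_equal(ge_minp(snp_res(p, matrix(1, 5, 5))), 0.01)
})

test_that("GATES reduces to Simes under independence", {
  expect_equal(ge_gates(snp_res(0.37, matrix(1, 1, 1))), 0.37)
  p <- c(0.01, 0.2, 0.5)
  simes <- min(3 * sort(p) / seq_len(3))
  expect_equal(ge_gates(snp_res(p, diag(3))), simes)
})

test_that("minP and GATES are invariant to duplicating a SNP column", {
  set.seed(43)
  G <- simulate_genotypes(400, 4, maf = c(0.2, 0.3, 0.25, 0.4), ld_rho = 0.5)
  X <- G$values
  z <- rnorm(400)
  y <- rnorm(400) + 0.3 * std_pop(X[, 2]) * std_pop(z)
  res <- snp_gxe_pvalues(y, X, z)
  Xdup <- cbind(X, X[, 2])
  res_dup <- snp_gxe_pvalues(y, Xdup, z)
  expect_lt(abs(ge_minp(res_dup) - ge_minp(res)), 0.01)
  expect_lt(abs(ge_gates(res_dup) - ge_gates(res)), 0.01)
})

test_that("truncation statistics match their closed forms", {
  expect_equal(tts_stat(c(0.2, 0.6, 0.9), tau = 0.05), 0)
  expect_equal(tts_stat(0.01, tau = 0.05), 1 - 0.01 * 2 / 1)
  expect_equal(tprod_stat(c(0.3, 0.9), tau = 0.05), 1)
  expect_equal(tprod_stat(c(0.01, 0.04, 0.5), tau = 0.05), 4e-4)
})

test_that("truncated-product permutation p matches Zaykin's formula under
           independence", {
  set.seed(44)
  diffs <- vapply(1:12, function(i) {
    N <- 300; K <- 5
    X <- random_genotypes(N, K)
    z <- rnorm(N)
    y <- rnorm(N)
    res <- snp_gxe_pvalues(y, X, z)
    nullp <- snp_gxe_perm_pvalues(y, X, z, n_perm = 499, seed = i)
    p_perm <- ge_tprod(res, nullp)
    p_analytic <- zaykin_tprod_p(tprod_stat(res$p_values, 0.05), K, 0.05)
    p_perm - p_analytic
  }, numeric(1))
  # each permutation p has Monte-Carlo sd <= 0.023 at B = 499
  expect_lt(max(abs(diffs)), 4 * sqrt(0.25 / 500))
  expect_lt(abs(mean(diffs)), 2 * sqrt(0.25 / 500 / 12))
})

test_that("tTS and tProd are valid and calibrated in the rejection tail", {
  # the truncation statistics are 0 for most null datasets (no SNP p-value
  # below tau), so their permutation p-values carry an atom near 1: the
  # whole distribution is sub-uniform, but the rejection tail at alpha =
  # 0.05 sits in the continuous part and must be calibrated
  set.seed(45)
  pvals <- t(vapply(1:150, function(i) {
    N <- 150; K <- 4
    X <- random_genotypes(N, K)
    z <- rnorm(N)
    y <- rnorm(N)
    res <- snp_gxe_pvalues(y, X, z)
    nullp <- snp_gxe_perm_pvalues(y, X, z, n_perm = 99, seed = i)
    c(ge_tts(res, nullp), ge_tprod(res, nullp))
  }, numeric(2)))
  ci <- qbinom(c(0.005, 0.995), 150, 0.05) / 150
  for (j in 1:2) {
    expect_gte(min(pvals[, j]), 0.01)   # add-one bound
    rate <- mean(pvals[, j] <= 0.05)
    expect_gte(rate, ci[1])
    expect_lte(rate, ci[2])
  }
})

test_that("all combiners return a p-value in [0, 1]", {
  set.seed(46)
  X <- random_genotypes(200, 5)
  z <- rnorm(200)
  y <- rnorm(200) + std_pop(X[, 1]) * std_pop(z)
  p4 <- gxe_combine(y, X, z, n_perm = 99, seed = 1)
  expect_named(p4, c("GE_minP", "GE_GATES", "GE_tTS", "GE_tProd"))
  expect_true(all(p4 >= 0 & p4 <= 1))
})
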