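# shared fixtures and independent oracles, built in code

# population-sd standardization (sum of squares == N), matching the model's
# internal convention
std_pop <- function(v) {
  vc <- v - mean(v)
  vc / sqrt(mean(vc^2))
}

std_pop_cols <- function(M) apply(M, 2L, std_pop)

# random genotype matrix with no structure, guaranteed polymorphic columns
random_genotypes <- function(N, K, maf = 0.3) {
  X <- matrix(rbinom(N * K, 2, maf), N, K)
  for (k in seq_len(K)) {
    while (stats::var(X[, k]) == 0) X[, k] <- rbinom(N, 2, maf)
  }
  X
}

# the penalized objective on the internal (unnormalized-w) parameterization,
# written independently of the package internals: par = (w_1..w_K, b1, b2,
# b12, b0); intercept unpenalized, w_E = 1 contributes lambda * 1
phi_reference <- function(par, yc, Xs, es, lambda, penalize_b = TRUE) {
  K <- ncol(Xs)
  w <- par[seq_len(K)]
  b <- par[K + 1:4]
  g <- as.numeric(Xs %*% w)
  res <- yc - b[1] * g - b[2] * es - b[3] * g * es - b[4]
  sum(res^2) + lambda * (sum(w^2) + 1) +
    (if (penalize_b) lambda else 0) * (b[1]^2 + b[2]^2 + b[3]^2)
}

# final objective value of a gxe_fit
phi_of_fit <- function(fit) utils::tail(fit$objective, 1)

# Zaykin's closed-form null distribution of the truncated p-value product
# for L independent uniform p-values: P(W <= w) at truncation tau
zaykin_tprod_p <- function(w, L, tau) {
  if (w >= 1) return(1)
  total <- 0
  for (k in seq_len(L)) {
    term <- if (w > tau^k) {
      tau^k
    } else {
      s <- 0:(k - 1)
      w * sum((k * log(tau) - log(w))^s / factorial(s))
    }
    total <- total + choose(L, k) * (1 - tau)^(L - k) * term
  }
  total
}

# Direct Benjamini-Hochberg step-up, written independently of p.adjust
bh_reference <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[ord] <- pmin(1, adj)
  out
}

# Exact HWE test by brute-force enumeration of heterozygote counts: the
# conditional probability of n_ab heterozygotes given minor-allele count is
# computed from first principles with exact log-gamma arithmetic.
hwe_bruteforce <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_aa + n_ab
  if (na > n) return(hwe_bruteforce(n_bb, n_ab, n_aa))
  if (na == 0) return(1)
  hs <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  # unnormalized conditional weights P(h) proportional to 2^h n!/(aa! h! bb!)
  pr <- vapply(hs, function(h) {
    aa <- (na - h) / 2
    bb <- n - aa - h
    exp(lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
          h * log(2))
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[hs == n_ab]
  sum(pr[pr <= obs * (1 + 1e-9)])
}

# Independent PLINK 1 .bed/.bim/.fam writer (SNP-major) used to exercise the
# reader: codes 00 = 2 copies of A1, 10 = 1, 11 = 0, 01 = missing.
write_plink_fixture <- function(vals, variants, samples, prefix) {
  N <- nrow(vals); K <- ncol(vals)
  code_of <- function(g) {
    if (is.na(g)) 1L else if (g == 2) 0L else if (g == 1) 2L else 3L
  }
  bytes <- raw(0)
  for (k in seq_len(K)) {
    codes <- vapply(vals[, k], code_of, integer(1))
    codes <- c(codes, rep(0L, (4 - N %% 4) %% 4))
    packed <- vapply(seq_len(length(codes) / 4), function(i) {
      c4 <- codes[(4 * i - 3):(4 * i)]
      as.raw(c4[1] + bitwShiftL(c4[2], 2) + bitwShiftL(c4[3], 4) +
               bitwShiftL(c4[4], 6))
    }, raw(1))
    bytes <- c(bytes, packed)
  }
  writeBin(c(as.raw(c(0x6c, 0x1b, 0x01)), bytes), paste0(prefix, ".bed"))
  write.table(data.frame(variants$chrom, variants$id, 0, variants$pos,
                         "A", "G"),
              paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(samples, samples, 0, 0, 0, -9),
              paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
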