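# shared internal helpers

# Column standardization with population (1/N) variance so that each
# standardized column x satisfies sum(x^2) == N exactly; this is what makes
# the latent-variable constraints sum(g^2) = sum(e^2) = N hold.
std_cols <- function(M, center = NULL, scale = NULL) {
  M <- as.matrix(M)
  if (is.null(center)) center <- colMeans(M)
  Mc <- sweep(M, 2L, center, "-")
  if (is.null(scale)) scale <- sqrt(colMeans(Mc^2))
  list(x = sweep(Mc, 2L, scale, "/"), center = center, scale = scale)
}

std_vec <- function(v, center = NULL, scale = NULL) {
  if (is.null(center)) center <- mean(v)
  vc <- v - center
  if (is.null(scale)) scale <- sqrt(mean(vc^2))
  list(x = vc / scale, center = center, scale = scale)
}

# Deterministic 31-bit seed stream for (master seed, string id) pairs, so
# per-gene results do not depend on gene processing order.
derive_seed <- function(seed, id) {
  h <- as.double(seed %% 2147483647L)
  for (b in utf8ToInt(as.character(id))) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h) + 1L
}

# Clopper-Pearson interval for a binomial proportion.
exact_binom_ci <- function(x, n, level = 0.95) {
  a <- (1 - level) / 2
  lo <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(lo, hi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
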