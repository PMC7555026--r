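#' Simulation configuration
#'
#' Bundles the knobs of the synthetic genotype/phenotype generator. The
#' defaults reproduce the study conditions of the package's power and
#' type-I-error experiments: 20\% causal SNPs with per-SNP weight
#' \eqn{w_k = 0.5}, main genetic effect \eqn{\beta_1 = 1}, environment
#' effect \eqn{\beta_2 = 1}, AR(1) latent LD with \eqn{\rho = 0.5}, per-SNP
#' minor allele frequencies drawn uniformly on \[0.05, 0.4\], and a
#' standard-normal environment. Setting `beta12 = 0` gives the null of no
#' gene-environment interaction.
#'
#' @param N sample size.
#' @param K number of SNPs in the gene.
#' @param maf per-SNP minor allele frequencies in \[0.01, 0.5\]; a scalar is
#'   recycled; `NULL` (default) draws each from U(0.05, 0.4) at generation.
#' @param ld_rho AR(1) correlation of the latent Gaussian haplotype field,
#'   in \[0, 1).
#' @param causal_fraction fraction of SNPs carrying the weight `w_k`
#'   (rounded to a count, minimum 1 when a genetic effect is present).
#' @param w_k effect size of each causal SNP.
#' @param beta0,beta1,beta2,beta12 intercept, gene, environment and
#'   interaction coefficients of the generating model.
#' @param env environment distribution: `"normal"` (standard normal) or
#'   `"binary"` (Bernoulli(0.5)).
#' @param seed RNG seed; a dataset is reproduced bit-exactly from its
#'   config.
#' @return object of class `"gxe_sim_config"`.
#' @export
sim_config <- function(N = 500, K = 5, maf = NULL, ld_rho = 0.5,
                       causal_fraction = 0.2, w_k = 0.5,
                       beta0 = 0, beta1 = 1, beta2 = 1, beta12 = 0,
                       env = c("normal", "binary"), seed = NULL) {
  env <- match.arg(env)
  stopifnot(N >= 2, K >= 1, ld_rho >= 0, ld_rho < 1,
            causal_fraction >= 0, causal_fraction <= 1)
  if (!is.null(maf)) {
    maf <- rep_len(maf, K)
    if (any(maf < 0.01 | maf > 0.5))
      stop("maf entries must lie in [0.01, 0.5]")
  }
  if ((beta1 != 0 || beta12 != 0) && round(causal_fraction * K) < 1 &&
      causal_fraction * K < 1)
    message("sim_config: causal count rounds below 1; a minimum of 1 causal ",
            "SNP is used because a genetic effect is present")
  structure(list(N = N, K = K, maf = maf, ld_rho = ld_rho,
                 causal_fraction = causal_fraction, w_k = w_k,
                 beta0 = beta0, beta1 = beta1, beta2 = beta2,
                 beta12 = beta12, env = env, seed = seed),
            class = "gxe_sim_config")
}

#' Simulate LD-structured common-variant genotypes
#'
#' Gaussian-copula generator: two independent haplotype draws per subject
#' from an AR(1)-correlated standard multivariate normal
#' (\eqn{corr(h_j, h_k) = \rho^{|j-k|}}); each latent column is thresholded
#' at the normal quantile of its minor allele frequency and the two allele
#' indicators are summed, so marginal genotype frequencies follow
#' Hardy-Weinberg proportions for the target MAF while adjacent SNPs show
#' LD that decays with distance.
#'
#' @param N samples.
#' @param K SNPs.
#' @param maf per-SNP minor allele frequencies (scalar recycled).
#' @param ld_rho AR(1) latent correlation in \[0, 1).
#' @param seed optional RNG seed.
#' @return a [genotype_matrix()] (chromosome `"1"`, positions 1 kb apart).
#' @export
simulate_genotypes <- function(N, K, maf = 0.3, ld_rho = 0.5, seed = NULL) {
  maf <- rep_len(maf, K)
  if (any(maf < 0.01 | maf > 0.5)) stop("maf entries must lie in [0.01, 0.5]")
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  thr <- stats::qnorm(maf)
  hap <- function() {
    H <- matrix(stats::rnorm(N * K), N, K)
    if (ld_rho > 0 && K > 1) {
      s <- sqrt(1 - ld_rho^2)
      for (k in 2:K) H[, k] <- ld_rho * H[, k - 1] + s * H[, k]
    }
    sweep(H, 2L, thr, "<") * 1
  }
  vals <- hap() + hap()
  genotype_matrix(vals,
                  variants = data.frame(chrom = "1",
                                        pos = 1000L * seq_len(K),
                                        id = paste0("snp", seq_len(K))),
                  samples = paste0("sample", seq_len(N)))
}

#' Simulate a phenotype with a latent gene-environment interaction
#'
#' Generates the environment and phenotype
#' \deqn{y_i = \beta_0 + \beta_1 \sum_k w_k x_{ik} + \beta_2 e_i +
#'   \beta_{12} (\sum_k w_k x_{ik}) e_i + \epsilon_i,}
#' with \eqn{w_k} equal to `config$w_k` on a randomly drawn causal subset
#' of `round(causal_fraction * K)` SNPs (minimum 1) and 0 elsewhere,
#' \eqn{e_i} the standardized environment, raw additive genotype codes
#' \eqn{x_{ik}}, and \eqn{\epsilon_i} standard normal.
#'
#' @param X a [genotype_matrix()] or plain genotype matrix.
#' @param config a [sim_config()].
#' @param noise_sd standard deviation of \eqn{\epsilon} (0 gives the
#'   noiseless linear combination exactly).
#' @return list with `y`, `z` (raw environment), `e` (standardized
#'   environment) and `causal_indices`.
#' @export
simulate_phenotype <- function(X, config, noise_sd = 1) {
  V <- if (inherits(X, "genotype_matrix")) X$values else as.matrix(X)
  N <- nrow(V)
  K <- ncol(V)
  stopifnot(inherits(config, "gxe_sim_config"))
  n_causal <- round(config$causal_fraction * K)
  if (config$beta1 != 0 || config$beta12 != 0) n_causal <- max(1, n_causal)
  causal <- if (n_causal > 0) sort(sample.int(K, n_causal)) else integer(0)
  wvec <- numeric(K)
  wvec[causal] <- config$w_k
  burden <- as.numeric(V %*% wvec)
  z <- switch(config$env,
              normal = stats::rnorm(N),
              binary = stats::rbinom(N, 1, 0.5))
  e <- std_vec(z)$x
  eps <- if (noise_sd > 0) stats::rnorm(N, 0, noise_sd) else numeric(N)
  y <- config$beta0 + config$beta1 * burden + config$beta2 * e +
    config$beta12 * burden * e + eps
  list(y = y, z = z, e = e, causal_indices = causal)
}

#' Simulate a complete dataset (genotypes, environment, phenotype)
#'
#' Seeds the RNG from `config$seed` (when set), draws MAFs if the config
#' left them free, then genotypes and phenotype. Bit-exactly reproducible
#' from the config.
#'
#' @param config a [sim_config()].
#' @return list with `genotypes` (a [genotype_matrix()]), `y`, `z`, `e`,
#'   `causal_indices`, `maf` and the `config`.
#' @export
simulate_gxe_dataset <- function(config) {
  stopifnot(inherits(config, "gxe_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  maf <- config$maf %||% stats::runif(config$K, 0.05, 0.4)
  G <- simulate_genotypes(config$N, config$K, maf, config$ld_rho)
  ph <- simulate_phenotype(G, config)
  c(list(genotypes = G, maf = maf, config = config), ph)
}
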