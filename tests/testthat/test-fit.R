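test_that("build_latents satisfies the standardization constraints", {
  set.seed(10)
  N <- 40
  X <- std_pop_cols(random_genotypes(N, 3))
  z <- std_pop(rnorm(N))
  lat <- build_latents(X, z, w = c(0.5, -1, 2))
  expect_equal(sum(lat$g^2), N)
  expect_equal(sum(lat$e^2), N)
  expect_equal(sum(lat$r^2), N)
  # back-normalization: w * scale["g"] reproduces g through X
  expect_equal(as.numeric(X %*% (c(0.5, -1, 2) * lat$scale["g"])), lat$g)
})

test_that("single-column latent is the standardized column itself", {
  set.seed(11)
  x <- std_pop(rbinom(30, 2, 0.4))
  z <- std_pop(rnorm(30))
  lat <- build_latents(matrix(x), z, w = 1)
  expect_equal(lat$g, x)
  # e is +/- standardized z depending on the sign of the environment weight
  expect_equal(build_latents(matrix(x), z, w = 1, w_env = 3)$e, z)
  expect_equal(build_latents(matrix(x), z, w = 1, w_env = -0.2)$e, -z)
})

test_that("hand-computed two-SNP latent on a 4-sample design", {
  X_raw <- matrix(c(1, -1, 0, 0, 0, 0, 1, -1), 4, 2)
  X <- std_pop_cols(X_raw)        # columns scaled so sum of squares = 4
  z <- std_pop(c(1, 2, 3, 4))
  lat <- build_latents(X, z, w = c(1, 1))
  # direct arithmetic: Xw = sqrt(2)*(1,-1,1,-1), rescaled to sum g^2 = 4
  expect_equal(lat$g, c(1, -1, 1, -1))
  expect_equal(sum(lat$g^2), 4)
})

test_that("degenerate weights raise an error", {
  X <- std_pop_cols(random_genotypes(20, 2))
  z <- std_pop(rnorm(20))
  expect_error(build_latents(X, z, w = c(0, 0)), "degenerate")
})

test_that("objective_phi computes the stated penalized sum of squares", {
  expect_equal(objective_phi(c(1, 2), c(1, 2), W = 1, B = 1, lambda_s = 0), 0)
  expect_equal(objective_phi(c(1, 1), c(0, 0), W = 1, B = 2, lambda_s = 0.5),
               4.5)
  expect_equal(objective_phi(c(1, 1), c(0, 0), W = 1, B = 2, lambda_s = 0.5,
                             penalize_b = FALSE), 2.5)
})

test_that("ALS solution beats 1000 random parameter draws", {
  set.seed(12)
  N <- 50; K <- 3
  X <- random_genotypes(N, K)
  z <- rnorm(N)
  y <- rnorm(N) + 0.5 * std_pop(X[, 1]) * std_pop(z)
  lambda <- 0.2
  fit <- gxe_fit(y, X, z, lambda = lambda)
  Xs <- std_pop_cols(X); es <- std_pop(z); yc <- y - mean(y)
  random_phis <- replicate(1000, phi_reference(rnorm(K + 4), yc, Xs, es,
                                               lambda))
  expect_lt(phi_of_fit(fit), min(random_phis))
})

test_that("with lambda = 0 and one SNP the fit reproduces OLS exactly", {
  set.seed(13)
  N <- 80
  x <- rbinom(N, 2, 0.35)
  z <- rnorm(N)
  y <- 1 + 0.5 * x + 0.4 * z + 0.3 * x * z + rnorm(N)
  fit <- gxe_fit(y, matrix(x), z, lambda = 0)
  xs <- std_pop(x); zs <- std_pop(z)
  ols <- lm(y ~ xs + zs + I(xs * zs))
  expect_lt(max(abs(fitted(ols) - fitted(fit))), 1e-8)
})

test_that("noiseless model data is recovered exactly at lambda = 0", {
  set.seed(14)
  N <- 150; K <- 4
  X <- random_genotypes(N, K)
  z <- rnorm(N)
  lat <- build_latents(std_pop_cols(X), std_pop(z), w = c(1, 0.5, -0.3, 2))
  y <- 2 + 1.1 * lat$g + 0.6 * lat$e + 0.45 * lat$r
  fit <- gxe_fit(y, X, z, lambda = 0)
  expect_lt(abs(coef(fit)[["interaction"]] - 0.45), 1e-4)
  expect_lt(abs(coef(fit)[["env"]] - 0.6), 1e-4)
  expect_lt(max(abs(residuals(fit))), 1e-4)
})

test_that("objective trace is monotone and constraints hold at the fit", {
  set.seed(15)
  for (lambda in c(0, 0.1, 0.5)) {
    N <- 60; K <- 5
    X <- random_genotypes(N, K)
    z <- rnorm(N)
    y <- rnorm(N)
    fit <- gxe_fit(y, X, z, lambda = lambda)
    expect_true(all(diff(fit$objective) <= 1e-8 * (1 + fit$objective[-1])))
    expect_equal(sum(fit$latents$g^2), N)
    expect_equal(sum(fit$latents$e^2), N)
    expect_equal(sum(fit$latents$r^2), N)
    expect_gt(sum(fit$weights), 0)   # sign convention
  }
})

test_that("different random initializations reach the same coefficients", {
  set.seed(16)
  N <- 100; K <- 4
  X <- random_genotypes(N, K)
  z <- rnorm(N)
  y <- 0.4 * std_pop(X[, 2]) + 0.3 * std_pop(z) +
    0.5 * std_pop(X[, 2]) * std_pop(z) + rnorm(N)
  # tight phi tolerance so the comparison probes identifiability, not the
  # stopping rule
  fits <- lapply(c(21, 99, 1234), function(s)
    gxe_fit(y, X, z, lambda = 0.2, init = "random", seed = s, tol = 1e-12))
  base <- coef(fits[[1]])[1:3]
  for (f in fits[-1])
    expect_equal(coef(f)[1:3], base, tolerance = 1e-5)
})

test_that("ridge shrinkage: SS(W) never increases with lambda", {
  set.seed(17)
  N <- 80; K <- 6
  X <- random_genotypes(N, K)
  z <- rnorm(N)
  y <- rnorm(N) + 0.3 * std_pop(X[, 1])
  # the penalty acts on the weights of the internal parameterization
  ssw <- vapply(c(0, 0.1, 0.2, 0.3, 0.4, 0.5), function(l)
    sum(gxe_fit(y, X, z, lambda = l)$w_internal^2), numeric(1))
  expect_true(all(diff(ssw) <= 1e-6 * (1 + ssw[-1])))
})

test_that("cross-validation respects grid contract and tie-breaks", {
  set.seed(18)
  N <- 60
  X <- random_genotypes(N, 3)
  z <- rnorm(N)
  y <- rnorm(N)
  cvs <- cv_lambda(y, X, z, grid = 0.3, seed = 1)
  expect_equal(cvs$chosen, 0.3)
  grid <- seq(0, 0.5, length.out = 15)
  expect_length(grid, 15)
  cvd <- cv_lambda(y, X, z, seed = 2)
  expect_length(cvd$grid, 15)
  expect_equal(range(cvd$grid), c(0, 0.5))
  expect_true(cvd$chosen %in% cvd$grid)
})

test_that("pure-noise phenotypes select a positive ridge penalty", {
  set.seed(19)
  chosen <- vapply(1:60, function(i) {
    X <- matrix(rbinom(50 * 20, 2, 0.3), 50, 20)
    z <- rnorm(50)
    y <- rnorm(50)
    cv_lambda(y, X, z, seed = i)$chosen
  }, numeric(1))
  expect_gte(mean(chosen > 0), 0.9)
})
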