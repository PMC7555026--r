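#' @export
print.gxe_fit <- function(x, digits = 4, ...) {
  cat("Latent-component G×E model fit\n")
  cat("  samples:", x$N, "  SNPs:", x$K,
      "  lambda_S:", format(x$lambda, digits = digits),
      if (!is.null(x$cv)) "(cross-validated)" else "", "\n")
  cat("  converged:", x$converged, "in", x$n_iter, "iterations\n")
  cat("Path coefficients:\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
summary.gxe_fit <- function(object, ...) {
  rss <- sum(object$residuals^2)
  tss <- sum((object$data$y)^2)
  structure(list(fit = object,
                 r.squared = 1 - rss / tss,
                 sigma = sqrt(rss / max(1, object$N - length(object$coefficients) -
                                          object$K)),
                 objective = utils::tail(object$objective, 1)),
            class = "summary.gxe_fit")
}

#' @export
print.summary.gxe_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("SNP weights (sum g^2 = N scale):\n")
  print(round(x$fit$weights, digits))
  cat("R-squared:", format(x$r.squared, digits = digits),
      "  residual sd:", format(x$sigma, digits = digits),
      "  phi:", format(x$objective, digits = digits), "\n")
  invisible(x)
}

#' @export
coef.gxe_fit <- function(object, ...) object$coefficients

#' @export
fitted.gxe_fit <- function(object, ...) object$fitted.values

#' @export
residuals.gxe_fit <- function(object, ...) object$residuals

#' Predict from a fitted latent-component G\eqn{\times}E model
#'
#' New genotypes, environment and covariates are standardized with the
#' statistics of the training data, mapped through the trained weights to
#' the latent components, and combined with the trained path coefficients.
#'
#' @param object a [gxe_fit()] object.
#' @param newdata list with elements `X` (genotype matrix), `z`
#'   (environment) and, if the model had covariates, `covariates`. When
#'   omitted, training fitted values are returned.
#' @param ... unused.
#' @return numeric vector of predicted phenotypes.
#' @export
predict.gxe_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  s <- object$scaling
  Xs <- std_cols(as.matrix(newdata$X), s$x_center, s$x_scale)$x
  e <- std_vec(as.numeric(newdata$z), s$z_center, s$z_scale)$x
  b <- object$coefficients
  g <- as.numeric(Xs %*% object$weights)
  r <- g * e * s$r_scale
  pred <- b[1] * g + b[2] * e + b[3] * r
  if (!is.null(s$c_center)) {
    if (is.null(newdata$covariates)) stop("model has covariates; supply them")
    Cs <- std_cols(as.matrix(newdata$covariates), s$c_center, s$c_scale)$x
    pred <- pred + as.numeric(Cs %*% b[-(1:3)])
  }
  pred + object$intercept
}

#' @export
plot.gxe_fit <- function(x, which = c("objective", "weights"), ...) {
  which <- match.arg(which)
  if (which == "objective") {
    plot(seq_along(x$objective), x$objective, type = "b", pch = 16,
         xlab = "ALS iteration", ylab = expression(phi),
         main = "Penalized objective trace", ...)
  } else {
    graphics::barplot(x$weights, las = 2, ylab = "weight",
                      main = "SNP weights", ...)
  }
  invisible(x)
}

#' Simulate phenotypes from a fitted model
#'
#' Draws Gaussian phenotypes around the fitted values with the residual
#' standard deviation of the fit.
#'
#' @param object a [gxe_fit()] object.
#' @param nsim number of replicate phenotype vectors.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return data frame with `nsim` columns, as [stats::simulate()].
#' @export
simulate.gxe_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  npar <- length(object$coefficients) + object$K
  sigma <- sqrt(sum(object$residuals^2) / max(1, object$N - npar))
  out <- as.data.frame(replicate(
    nsim, object$fitted.values + stats::rnorm(object$N, 0, sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
print.gxe_cv <- function(x, digits = 4, ...) {
  cat("Cross-validation of lambda_S (", x$folds, "folds )\n")
  tab <- data.frame(lambda = x$grid, cv_error = x$cv_error)
  print(format(tab, digits = digits), row.names = FALSE)
  cat("chosen:", format(x$chosen, digits = digits), "\n")
  invisible(x)
}

#' @export
plot.gxe_cv <- function(x, ...) {
  plot(x$grid, x$cv_error, type = "b", pch = 16,
       xlab = expression(lambda[S]), ylab = "CV prediction error", ...)
  graphics::abline(v = x$chosen, lty = 2)
  invisible(x)
}

#' @export
print.gxe_perm <- function(x, digits = 4, ...) {
  cat("Phenotype-permutation test of the latent interaction (H0: beta12 = 0)\n")
  cat("  |beta12| observed:", format(x$observed_stat, digits = digits), "\n")
  cat("  permutations:", x$n_perm,
      " non-converged:", x$n_nonconverged,
      if (isTRUE(x$flagged)) "(FLAGGED: >5% failures)" else "", "\n")
  cat("  p-value:", format(x$p_value, digits = digits), "\n")
  invisible(x)
}
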