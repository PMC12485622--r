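# S3 methods for rkhs_fit objects.

#' @export
print.rkhs_fit <- function(x, ...) {
  cat("Multi-kernel Bayesian RKHS fit\n")
  cat(sprintf("  %d lines (%d masked), %d kernel term(s), %d retained draws (%d chain(s))\n",
              x$n, length(x$mask), length(x$terms), x$retained_draws, x$n_chains))
  vc <- x$varcomp
  cat("  Variance components (posterior mean):\n")
  for (i in seq_len(nrow(vc))) {
    cat(sprintf("    %-10s %8.4f\n", vc$term[i], vc$mean[i]))
  }
  cat(sprintf("    %-10s %8.4f\n", "residual", x$resid_var["mean"]))
  h <- heritability(x)
  cat(sprintf("  Heritability (VP / (VP + Ve)): %.3f\n", h$h2))
  invisible(x)
}

#' @export
summary.rkhs_fit <- function(object, ...) {
  vc <- object$varcomp
  tab <- rbind(
    data.frame(term = vc$term, mean = vc$mean, sd = vc$sd, rhat = vc$rhat),
    data.frame(term = "residual",
               mean = object$resid_var[["mean"]],
               sd = object$resid_var[["sd"]],
               rhat = object$resid_var[["rhat"]])
  )
  h <- heritability(object)
  out <- list(varcomp = tab, mu = object$mu, h2 = h$h2, VP = h$VP, Ve = h$Ve,
              n = object$n, n_masked = length(object$mask),
              retained_draws = object$retained_draws,
              n_chains = object$n_chains)
  class(out) <- "summary.rkhs_fit"
  out
}

#' @export
print.summary.rkhs_fit <- function(x, digits = 4, ...) {
  cat("Multi-kernel Bayesian RKHS fit\n")
  cat(sprintf("n = %d (masked: %d), retained draws = %d, chains = %d\n\n",
              x$n, x$n_masked, x$retained_draws, x$n_chains))
  tab <- x$varcomp
  tab$mean <- signif(tab$mean, digits)
  tab$sd <- signif(tab$sd, digits)
  tab$rhat <- signif(tab$rhat, 4)
  print(tab, row.names = FALSE)
  cat(sprintf("\nIntercept: %.4f   VP = %.4f   Ve = %.4f   h2 = %.4f\n",
              x$mu[["mean"]], x$VP, x$Ve, x$h2))
  invisible(x)
}

#' Posterior-mean variance components
#'
#' @param object An `rkhs_fit`.
#' @param ... Unused.
#' @return Named vector of per-term variance components plus `resid_var`.
#' @export
coef.rkhs_fit <- function(object, ...) {
  stats::setNames(c(object$varcomp$mean, object$resid_var[["mean"]]),
                  c(object$varcomp$term, "resid_var"))
}

#' @export
fitted.rkhs_fit <- function(object, ...) object$fitted

#' Predicted phenotypes for masked lines
#'
#' Posterior mean of `mu + sum_k u_k` at the masked (test) indices; with
#' `which = "all"`, at every line.
#'
#' @param object An `rkhs_fit`.
#' @param which `"masked"` (default) or `"all"`.
#' @param ... Unused.
#' @export
predict.rkhs_fit <- function(object, which = c("masked", "all"), ...) {
  which <- match.arg(which)
  if (which == "all") object$fitted else object$predictions
}

#' @export
residuals.rkhs_fit <- function(object, ...) {
  obs <- setdiff(seq_len(object$n), object$mask)
  object$y[obs] - object$fitted[obs]
}

#' Trace plots of the variance-component draws
#'
#' @param x An `rkhs_fit`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.rkhs_fit <- function(x, ...) {
  pars <- colnames(x$draws[[1]])
  old <- graphics::par(mfrow = c(ceiling(length(pars) / 2), 2),
                       mar = c(3, 3, 2, 1))
  on.exit(graphics::par(old))
  for (p in pars) {
    tr <- sapply(x$draws, function(d) d[, p])
    graphics::matplot(tr, type = "l", lty = 1, main = p,
                      xlab = "retained draw", ylab = p, ...)
  }
  invisible(x)
}

#' Simulate phenotypes from a fitted model
#'
#' Draws new phenotype vectors from the model at the posterior-mean
#' parameter values: `y* = mu + sum_k u_k* + e*` with
#' `u_k* ~ N(0, sigma2_k K_k)` and `e* ~ N(0, sigma2_e I)`. Requires the
#' kernel list (stored when the fit was made with `keep_kernels = TRUE`,
#' or supplied here).
#'
#' @param object An `rkhs_fit`.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional RNG seed.
#' @param kernels Kernel list; defaults to the one stored in the fit.
#' @param ... Unused.
#' @return An n x nsim matrix.
#' @export
simulate.rkhs_fit <- function(object, nsim = 1, seed = NULL, kernels = NULL, ...) {
  kernels <- kernels %||% object$kernels
  if (is.null(kernels))
    .stopf("simulate: refit with keep_kernels = TRUE or pass 'kernels'")
  if (!is.null(seed)) set.seed(seed)
  factors <- lapply(kernels, eigen_prepare,
                    min_eigen_keep = object$config$min_eigen_keep)
  s2 <- object$varcomp$mean
  out <- matrix(NA_real_, object$n, nsim)
  for (s in seq_len(nsim)) {
    y <- rep(object$mu[["mean"]], object$n)
    for (k in seq_along(factors)) {
      f <- factors[[k]]
      y <- y + f$vectors %*% (sqrt(s2[k] * f$values) * stats::rnorm(f$rank))
    }
    out[, s] <- y + stats::rnorm(object$n, 0, sqrt(object$resid_var[["mean"]]))
  }
  rownames(out) <- names(object$fitted)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
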