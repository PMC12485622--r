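# Multi-kernel Bayesian RKHS regression fitted by Gibbs sampling.
#
# Model: y = 1*mu + sum_k u_k + e, with u_k ~ N(0, sigma2_k K_k) for each
# kernel term and e ~ N(0, sigma2_e I). Each kernel is eigendecomposed once
# (K = G L G') and the effect reparameterized as u_k = G L^{1/2} b_k with
# b_k ~ N(0, sigma2_k I), giving diagonal Gaussian full conditionals for
# b_k. Variances carry scaled-inverse-chi-square priors; the intercept is
# flat; masked phenotypes are sampled by data augmentation, so predictions
# for test lines are posterior means of mu + sum_k u_k.

#' Spectral preparation of a kernel
#'
#' Eigendecomposes a symmetric PSD kernel and drops eigenpairs below a
#' relative threshold, returning the factor used by the sampler
#' (`u = vectors %*% (sqrt(values) * b)`).
#'
#' @param K Symmetric PSD kernel (run [psd_repair()] first if in doubt).
#' @param min_eigen_keep Relative eigenvalue threshold; eigenpairs with
#'   `value < min_eigen_keep * max(value)` are dropped.
#' @return List with `vectors` (n x r), `values` (length r) and `rank`.
#' @export
eigen_prepare <- function(K, min_eigen_keep = 1e-8) {
  if (any(!is.finite(K))) .stopf("eigen_prepare: non-finite kernel entries")
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  keep <- e$values >= min_eigen_keep * max(e$values) & e$values > 0
  if (!any(keep)) .stopf("eigen_prepare: kernel has no positive eigenvalues")
  list(vectors = e$vectors[, keep, drop = FALSE],
       values = e$values[keep],
       rank = sum(keep))
}

# One Gibbs chain. Returns retained draws of mu, per-term variances,
# residual variance, plus running sums for effect/prediction summaries.
.gibbs_chain <- function(y, mask, factors, n_iter, burn_in, thin,
                         prior_df, S0_terms, S0_resid, seed,
                         fixed_varcomp = NULL, fixed_resid = NULL) {
  set.seed(seed)
  n <- length(y)
  K <- length(factors)
  obs <- setdiff(seq_len(n), mask)

  y_aug <- y
  y_aug[mask] <- mean(y[obs])
  mu <- mean(y[obs])
  b <- lapply(factors, function(f) numeric(f$rank))
  u <- matrix(0, n, K)
  s2k <- if (is.null(fixed_varcomp)) S0_terms / (prior_df + 2) else fixed_varcomp
  s2e <- if (is.null(fixed_resid)) S0_resid / (prior_df + 2) else fixed_resid

  r <- y_aug - mu            # residual y_aug - mu - sum(u); u starts at 0
  n_keep <- length(seq.int(burn_in + 1L, n_iter, by = thin))
  draw_mu <- numeric(n_keep)
  draw_s2 <- matrix(NA_real_, n_keep, K)
  draw_se <- numeric(n_keep)
  # Effect and prediction summaries accumulate the Gaussian full-conditional
  # means (Rao-Blackwellized posterior-mean estimates), not the sampled
  # effects: same limit, much smaller Monte-Carlo error.
  u_cond <- matrix(0, n, K)
  mu_cond <- mu
  sum_u <- matrix(0, n, K)
  sum_g <- numeric(n)        # mu + sum_k u_k
  kept <- 0L

  for (it in seq_len(n_iter)) {
    # intercept (flat prior)
    r_mu <- r + mu
    mu_cond <- mean(r_mu)
    mu <- stats::rnorm(1, mu_cond, sqrt(s2e / n))
    r <- r_mu - mu

    # per-term eigenbasis coefficients
    for (k in seq_len(K)) {
      f <- factors[[k]]
      r_k <- r + u[, k]
      t_k <- sqrt(f$values) * crossprod(f$vectors, r_k)[, 1]
      prec <- f$values / s2e + 1 / s2k[k]
      mean_b <- (t_k / s2e) / prec
      b[[k]] <- stats::rnorm(f$rank, mean_b, sqrt(1 / prec))
      ub <- f$vectors %*% cbind(sqrt(f$values) * b[[k]],
                                sqrt(f$values) * mean_b)
      u[, k] <- ub[, 1]
      u_cond[, k] <- ub[, 2]
      r <- r_k - u[, k]
      if (is.null(fixed_varcomp)) {
        s2k[k] <- (S0_terms[k] + sum(b[[k]]^2)) /
          stats::rchisq(1, prior_df + f$rank)
      }
    }

    # residual variance
    if (is.null(fixed_resid)) {
      s2e <- (S0_resid + sum(r^2)) / stats::rchisq(1, prior_df + n)
    }

    # data augmentation for masked phenotypes
    if (length(mask)) {
      gmask <- mu + rowSums(u[mask, , drop = FALSE])
      y_aug[mask] <- stats::rnorm(length(mask), gmask, sqrt(s2e))
      r[mask] <- y_aug[mask] - gmask
    }

    if (it > burn_in && (it - burn_in - 1L) %% thin == 0L) {
      kept <- kept + 1L
      draw_mu[kept] <- mu
      draw_s2[kept, ] <- s2k
      draw_se[kept] <- s2e
      sum_u <- sum_u + u_cond
      sum_g <- sum_g + mu_cond + rowSums(u_cond)
    }
  }

  list(mu = draw_mu[seq_len(kept)],
       s2 = draw_s2[seq_len(kept), , drop = FALSE],
       se = draw_se[seq_len(kept)],
       mean_u = sum_u / kept,
       mean_g = sum_g / kept,
       retained = kept)
}

#' Fit a multi-kernel Bayesian RKHS regression
#'
#' Fits `y = 1 mu + sum_k u_k + e` with `u_k ~ N(0, sigma2_k K_k)` and
#' `e ~ N(0, sigma2_e I)` by Gibbs sampling. Entries of `y` that are `NA`
#' (or listed in `mask`) are treated as missing and predicted by data
#' augmentation — the cross-validation protocol for test lines.
#'
#' Every variance component has a scaled-inverse-chi-square prior with
#' `prior_df` degrees of freedom; prior scales allocate a fraction
#' `prior_R2` of the observed phenotypic variance equally across kernel
#' terms and `1 - prior_R2` to the residual. The intercept has a flat
#' prior.
#'
#' @param y Numeric phenotype vector; `NA` entries are predicted.
#' @param kernels Named list of n x n PSD kernel matrices, all on the same
#'   line ordering as `y`.
#' @param mask Optional integer indices to treat as missing in addition to
#'   `NA`s.
#' @param n_iter,burn_in,thin MCMC budget (defaults 6000 / 1000 / 5; at
#'   least 50 retained draws are required).
#' @param prior_df Prior degrees of freedom for every variance.
#' @param prior_R2 Prior fraction of phenotypic variance attributed to the
#'   kernel terms jointly.
#' @param n_chains Number of independent chains; with 2 or more, the
#'   Gelman-Rubin statistic is reported per variance parameter.
#' @param seed Master seed; per-chain substreams are derived from it.
#' @param min_eigen_keep Relative eigenvalue cutoff in [eigen_prepare()].
#' @param fixed_varcomp,fixed_resid Optional fixed values for the term and
#'   residual variances (no sampling of variances); used for conjugate
#'   checks against closed-form BLUP.
#' @param keep_kernels Store the kernel list in the fit (needed by
#'   [simulate.rkhs_fit()]).
#' @return Object of class `rkhs_fit`. Key elements: `varcomp` (data frame
#'   of per-term posterior means/sds and R-hat), `resid_var`, `mu`,
#'   `line_effects` (n x K posterior-mean effects), `fitted` (posterior
#'   mean of `mu + sum_k u_k`), `predictions` (fitted values at the masked
#'   indices), `draws` (per-chain variance draws).
#' @export
rkhs_fit <- function(y, kernels, mask = NULL,
                     n_iter = 6000, burn_in = 1000, thin = 5,
                     prior_df = 5, prior_R2 = 0.5,
                     n_chains = 1, seed = 1, min_eigen_keep = 1e-8,
                     fixed_varcomp = NULL, fixed_resid = NULL,
                     keep_kernels = FALSE) {
  if (!is.list(kernels) || length(kernels) == 0L)
    .stopf("rkhs_fit: 'kernels' must be a non-empty list")
  if (is.null(names(kernels)) || any(names(kernels) == ""))
    names(kernels) <- paste0("K", seq_along(kernels))
  n <- length(y)
  for (nm in names(kernels)) {
    if (!identical(dim(kernels[[nm]]), c(n, n)))
      .stopf("kernel '%s' is not %d x %d", nm, n, n)
  }
  mask <- sort(unique(c(which(is.na(y)), as.integer(mask))))
  obs <- setdiff(seq_len(n), mask)
  if (length(obs) < 2L || .is_constant(y[obs]))
    .stopf("rkhs_fit: observed phenotypes are constant or fewer than 2")
  if (burn_in >= n_iter) .stopf("rkhs_fit: burn_in must be < n_iter")
  n_keep <- length(seq.int(burn_in + 1L, n_iter, by = thin))
  if (n_keep < 50L)
    .stopf("rkhs_fit: only %d retained draws; increase n_iter", n_keep)
  if (!is.null(fixed_varcomp) && length(fixed_varcomp) != length(kernels))
    .stopf("fixed_varcomp must have one value per kernel")

  K <- length(kernels)
  vy <- stats::var(y[obs])
  # prior mode S0/(df + 2) targets the allocated variance share
  S0_terms <- rep(vy * prior_R2 / K * (prior_df + 2), K)
  S0_resid <- vy * (1 - prior_R2) * (prior_df + 2)
  factors <- lapply(kernels, eigen_prepare, min_eigen_keep = min_eigen_keep)

  chains <- lapply(seq_len(n_chains), function(ch) {
    .gibbs_chain(y, mask, factors, n_iter, burn_in, thin,
                 prior_df, S0_terms, S0_resid,
                 seed = .substream(seed, "chain", ch),
                 fixed_varcomp = fixed_varcomp, fixed_resid = fixed_resid)
  })

  all_s2 <- do.call(rbind, lapply(chains, `[[`, "s2"))
  all_se <- unlist(lapply(chains, `[[`, "se"))
  all_mu <- unlist(lapply(chains, `[[`, "mu"))
  rhat <- rep(NA_real_, K + 1)
  if (n_chains >= 2L) {
    for (k in seq_len(K)) {
      rhat[k] <- gelman_rubin(lapply(chains, function(c) c$s2[, k]))
    }
    rhat[K + 1] <- gelman_rubin(lapply(chains, `[[`, "se"))
  }

  mean_u <- Reduce(`+`, lapply(chains, `[[`, "mean_u")) / n_chains
  mean_g <- Reduce(`+`, lapply(chains, `[[`, "mean_g")) / n_chains
  colnames(mean_u) <- names(kernels)
  ids <- rownames(kernels[[1]])
  if (!is.null(ids)) { names(mean_g) <- ids; rownames(mean_u) <- ids }

  fit <- list(
    terms = names(kernels),
    n = n, mask = mask, y = y,
    varcomp = data.frame(
      term = names(kernels),
      mean = colMeans(all_s2),
      sd = apply(all_s2, 2, stats::sd),
      rhat = rhat[seq_len(K)],
      row.names = NULL),
    resid_var = c(mean = mean(all_se), sd = stats::sd(all_se),
                  rhat = rhat[K + 1]),
    mu = c(mean = mean(all_mu), sd = stats::sd(all_mu)),
    line_effects = mean_u,
    fitted = mean_g,
    predictions = mean_g[mask],
    retained_draws = length(all_se),
    n_chains = n_chains,
    draws = lapply(chains, function(c) {
      d <- cbind(c$s2, c$se, c$mu)
      colnames(d) <- c(names(kernels), "resid_var", "mu")
      d
    }),
    config = list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                  prior_df = prior_df, prior_R2 = prior_R2, seed = seed,
                  min_eigen_keep = min_eigen_keep,
                  fixed_varcomp = fixed_varcomp, fixed_resid = fixed_resid)
  )
  if (keep_kernels) fit$kernels <- kernels
  class(fit) <- "rkhs_fit"
  fit
}

#' Gelman-Rubin potential scale reduction factor
#'
#' `sqrt(((m - 1)/m * W + B/m) / W)` for chains of common length `m`, with
#' `W` the mean within-chain variance and `B` the between-chain variance
#' (`m` times the variance of the chain means). Values near 1 indicate
#' convergence; the usual gate is R-hat < 1.1.
#'
#' @param chains List (or matrix columns) of two or more equal-length draw
#'   sequences for one parameter.
#' @return The R-hat statistic.
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  if (length(chains) < 2L) .stopf("gelman_rubin: need at least 2 chains")
  m <- unique(lengths(chains))
  if (length(m) != 1L) .stopf("gelman_rubin: chains must have equal length")
  if (m < 10L) .stopf("gelman_rubin: chains too short (%d draws)", m)
  means <- vapply(chains, mean, 1)
  W <- mean(vapply(chains, stats::var, 1))
  B <- m * stats::var(means)
  if (W <= 0) return(if (B <= 0) 1 else Inf)
  sqrt(((m - 1) / m * W + B / m) / W)
}
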