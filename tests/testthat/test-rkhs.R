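test_that("eigen_prepare reconstructs the kernel and drops null space", {
  I5 <- diag(5)
  f <- eigen_prepare(I5)
  expect_equal(f$values, rep(1, 5))
  expect_identical(f$rank, 5L)

  v <- rnorm(6)
  f <- eigen_prepare(tcrossprod(v))
  expect_identical(f$rank, 1L)

  K <- random_psd(10, seed = 21)
  f <- eigen_prepare(K)
  recon <- f$vectors %*% (f$values * t(f$vectors))
  expect_lt(norm(recon - K, "F") / norm(K, "F"), 1e-6)

  bad <- diag(3); bad[1, 1] <- NA
  expect_error(eigen_prepare(bad), "non-finite")
})

test_that("fixed-variance posterior means match the ridge closed form (K = I)", {
  set.seed(31)
  n <- 30
  y <- rnorm(n, 2, 1)
  K <- diag(n); dimnames(K) <- list(paste0("L", 1:n), paste0("L", 1:n))
  s2g <- 0.6; s2e <- 0.4; lam <- s2e / s2g
  fit <- rkhs_fit(y, list(g = K), n_iter = 6000, burn_in = 1000, thin = 1,
                  fixed_varcomp = s2g, fixed_resid = s2e, seed = 2)
  ridge <- (y - mean(y)) / (1 + lam)
  expect_lt(max(abs(fit$line_effects[, 1] - ridge)), 0.02)
})

test_that("fixed-variance posterior means match GBLUP for a general kernel", {
  set.seed(32)
  n <- 40
  geno <- simulate_genotypes(n, 150, seed = 3)
  K <- scale_kernel(vanraden_kernel(geno))
  f <- eigen_prepare(K)
  y <- as.numeric(1 + f$vectors %*% (sqrt(0.5 * f$values) * rnorm(f$rank)) +
                    rnorm(n, 0, sqrt(0.5)))
  s2g <- 0.5; s2e <- 0.5; lam <- s2e / s2g
  fit <- rkhs_fit(y, list(g = K), n_iter = 3000, burn_in = 500, thin = 1,
                  fixed_varcomp = s2g, fixed_resid = s2e, seed = 4)
  blup <- as.numeric(K %*% solve(K + lam * diag(n), y - mean(y)))
  expect_lt(max(abs(fit$line_effects[, 1] - blup)), 0.02)
})

test_that("masked predictions match the partitioned BLUP closed form", {
  set.seed(33)
  n <- 40
  geno <- simulate_genotypes(n, 150, seed = 6)
  K <- scale_kernel(vanraden_kernel(geno))
  f <- eigen_prepare(K)
  y <- as.numeric(f$vectors %*% (sqrt(0.7 * f$values) * rnorm(f$rank)) +
                    rnorm(n, 0, sqrt(0.3)))
  test <- sort(sample.int(n, 15))
  train <- setdiff(seq_len(n), test)
  s2g <- 0.7; s2e <- 0.3
  fit <- rkhs_fit(y, list(g = K), mask = test,
                  n_iter = 21000, burn_in = 1000, thin = 4,
                  fixed_varcomp = s2g, fixed_resid = s2e, seed = 8)
  # oracle: GLS intercept + train-conditional kernel regression
  Ktr <- K[train, train]; Vtr <- s2g * Ktr + s2e * diag(length(train))
  Vi <- solve(Vtr)
  mu <- sum(Vi %*% y[train]) / sum(Vi)
  pred <- mu + s2g * K[test, train] %*% Vi %*% (y[train] - mu)
  expect_lt(max(abs(fit$predictions - as.numeric(pred))), 0.03)
  expect_identical(names(fit$predictions), rownames(K)[test])
})

test_that("empty mask yields no predictions; null data give null accuracy", {
  ds <- tiny_dataset()
  y <- standardize_trait(ds$phenotypes[, 1])
  base <- build_base_kernels(ds, models = "M1")
  fit <- do.call(rkhs_fit, c(list(y = y, kernels = base["gL"], seed = 1),
                             fast_mcmc))
  expect_length(fit$predictions, 0)

  # pure-noise phenotype: test-set correlation hovers near zero
  set.seed(9)
  ynull <- rnorm(length(y))
  test <- 1:20
  fitn <- do.call(rkhs_fit, c(list(y = ynull, kernels = base["gL"],
                                   mask = test, seed = 2), fast_mcmc))
  expect_lt(abs(cor(ynull[test], fitn$predictions)), 0.5)
})

test_that("the sampler rejects degenerate inputs", {
  K <- diag(10); dimnames(K) <- list(paste0("L", 1:10), paste0("L", 1:10))
  expect_error(rkhs_fit(rep(1, 10), list(K)), "constant")
  expect_error(rkhs_fit(rnorm(10), list(K), n_iter = 100, burn_in = 50,
                        thin = 5), "retained draws")
  expect_error(rkhs_fit(rnorm(10), list(K[1:5, 1:5])), "not 10 x 10")
})

test_that("scaling the phenotype scales variance draws by c^2 exactly", {
  set.seed(35)
  n <- 25
  K <- random_psd(n, seed = 12)
  y <- rnorm(n)
  f1 <- do.call(rkhs_fit, c(list(y = y, kernels = list(g = K), seed = 5),
                            fast_mcmc))
  f2 <- do.call(rkhs_fit, c(list(y = 3 * y, kernels = list(g = K), seed = 5),
                            fast_mcmc))
  expect_equal(f2$varcomp$mean, 9 * f1$varcomp$mean, tolerance = 1e-10)
  expect_equal(f2$resid_var[["mean"]], 9 * f1$resid_var[["mean"]],
               tolerance = 1e-10)
  expect_equal(f2$mu[["mean"]], 3 * f1$mu[["mean"]], tolerance = 1e-10)
})

test_that("permuting lines permutes fixed-variance effect estimates", {
  set.seed(36)
  n <- 30
  geno <- simulate_genotypes(n, 100, seed = 13)
  K <- scale_kernel(vanraden_kernel(geno))
  y <- rnorm(n)
  perm <- sample.int(n)
  f1 <- rkhs_fit(y, list(g = K), n_iter = 1500, burn_in = 500, thin = 1,
                 fixed_varcomp = 0.5, fixed_resid = 0.5, seed = 3)
  f2 <- rkhs_fit(y[perm], list(g = K[perm, perm]),
                 n_iter = 1500, burn_in = 500, thin = 1,
                 fixed_varcomp = 0.5, fixed_resid = 0.5, seed = 3)
  expect_equal(unname(f2$line_effects[, 1]),
               unname(f1$line_effects[perm, 1]), tolerance = 1e-6)
})

test_that("gelman_rubin behaves at its analytic anchors", {
  # identical chains: B = 0, so R-hat = sqrt((m - 1) / m), i.e. 1 up to
  # the finite-sample factor
  x <- rnorm(1000)
  expect_equal(gelman_rubin(list(x, x)), 1, tolerance = 1e-3)
  expect_lte(gelman_rubin(list(x, x)), 1)
  set.seed(41)
  expect_lt(gelman_rubin(list(rnorm(1000), rnorm(1000))), 1.1)
  expect_gt(gelman_rubin(list(rnorm(1000), rnorm(1000, 10))), 3)
  expect_error(gelman_rubin(list(x)), "at least 2 chains")
  expect_error(gelman_rubin(list(x, x[1:10])), "equal length")
})

test_that("rkhs_fit S3 methods are coherent", {
  ds <- tiny_dataset()
  y <- standardize_trait(ds$phenotypes[, 1])
  base <- build_base_kernels(ds, models = "M4")
  kern <- materialize_kernels("M4", base)
  fit <- do.call(rkhs_fit, c(list(y = y, kernels = kern, seed = 7,
                                  n_chains = 2, keep_kernels = TRUE),
                             fast_mcmc))
  expect_s3_class(fit, "rkhs_fit")
  cf <- coef(fit)
  expect_named(cf, c("gL", "tL", "mL", "resid_var"))
  expect_true(all(cf > 0))
  expect_length(fitted(fit), length(y))
  expect_length(residuals(fit), length(y))
  expect_equal(residuals(fit), y - fitted(fit), ignore_attr = TRUE)
  expect_output(print(fit), "Heritability")
  s <- summary(fit)
  expect_s3_class(s, "summary.rkhs_fit")
  expect_false(any(is.na(s$varcomp$rhat)))
  sim <- simulate(fit, nsim = 3, seed = 1)
  expect_identical(dim(sim), c(fit$n, 3L))
  # simulated traits have roughly the fitted total variance
  expect_gt(var(sim[, 1]), 0)
  h <- heritability(fit)
  expect_equal(h$VP, sum(fit$varcomp$mean))
  expect_gt(h$h2, 0); expect_lt(h$h2, 1)
})
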