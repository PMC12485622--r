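test_that("linear_kernel matches the elementwise cross-product oracle", {
  X <- matrix(c(1, -1, -1, 1), 2, 2, dimnames = list(c("a", "b"), NULL))
  K <- linear_kernel(X)
  expect_equal(unclass(K), matrix(c(1, -1, -1, 1), 2, 2),
               ignore_attr = TRUE)

  set.seed(7)
  X <- matrix(rnorm(15), 5, 3)
  K <- linear_kernel(X)
  oracle <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    for (k in 1:3) oracle[i, j] <- oracle[i, j] + X[i, k] * X[j, k] / 3
  }
  expect_equal(unclass(K), oracle, tolerance = 1e-12, ignore_attr = TRUE)
  expect_gte(min_eig(K), -1e-10 * max_eig(K))

  zeros <- matrix(0, 3, 2)
  expect_equal(max(abs(linear_kernel(zeros))), 0)
})

test_that("vanraden_kernel follows the allele-frequency-centered formula", {
  M <- matrix(c(0, 1, 2, 2, 1, 0), 3, 2,
              dimnames = list(c("L1", "L2", "L3"), c("m1", "m2")))
  # by hand: p = (0.5, 0.5); denominator 2 * (0.25 + 0.25) = 1
  Z <- sweep(M, 2, c(1, 1), "-")
  expect_equal(unclass(vanraden_kernel(M)), tcrossprod(Z) / 1,
               ignore_attr = TRUE)

  mono <- matrix(2, 4, 3)
  expect_error(vanraden_kernel(mono), "monomorphic")

  set.seed(2)
  M <- matrix(rbinom(40 * 25, 2, 0.3), 40, 25)
  K <- vanraden_kernel(M)
  expect_equal(unclass(K), t(unclass(K)), ignore_attr = TRUE)
  expect_gte(min_eig(K), -1e-10 * max_eig(K))
})

test_that("gaussian_kernel uses the off-diagonal median bandwidth", {
  # n = 2: the single off-diagonal squared distance is its own median
  X <- rbind(c(0, 0), c(1, 0))
  K <- gaussian_kernel(X)
  expect_equal(K[1, 2], exp(-1))
  expect_equal(diag(unclass(K)), c(1, 1), ignore_attr = TRUE)
  expect_equal(attr(K, "bandwidth"), 1)

  set.seed(5)
  X <- matrix(rnorm(12), 4, 3)
  K <- gaussian_kernel(X)
  d2 <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) d2[i, j] <- sum((X[i, ] - X[j, ])^2)
  sigma <- median(d2[upper.tri(d2)])
  expect_equal(unclass(K), exp(-d2 / sigma), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(K > 0 & K <= 1))

  same <- rbind(c(1, 1), c(1, 1), c(1, 1))
  expect_error(gaussian_kernel(same), "degenerate bandwidth")
})

test_that("hybrid_kernels splits the product into CC/PP triangles", {
  I4 <- diag(4); dimnames(I4) <- list(letters[1:4], letters[1:4])
  hy <- hybrid_kernels(I4, I4)
  expect_equal(unclass(hy$CC), 2 * diag(4), ignore_attr = TRUE)
  expect_equal(max(abs(hy$PP)), 0)

  # hand-checked 3x3: triangles of P = K1 K2, diagonal assigned to UT
  K1 <- matrix(c(2, 1, 0, 1, 2, 1, 0, 1, 2), 3, 3)
  K2 <- matrix(c(1, 0.5, 0.2, 0.5, 1, 0.5, 0.2, 0.5, 1), 3, 3)
  dimnames(K1) <- dimnames(K2) <- list(1:3, 1:3)
  P <- K1 %*% K2
  UT <- P * upper.tri(P, diag = TRUE)
  LT <- P * lower.tri(P)
  hy <- hybrid_kernels(K1, K2)
  expect_equal(unclass(hy$CC), UT + t(UT), ignore_attr = TRUE)
  expect_equal(unclass(hy$PP), LT + t(LT), ignore_attr = TRUE)

  K3 <- random_psd(4)
  expect_error(hybrid_kernels(K1, K3), "dimension mismatch")
})

test_that("CC + PP = P + P' holds entrywise for random PSD pairs", {
  for (i in 1:25) {
    n <- sample(3:12, 1)
    K1 <- random_psd(n, seed = 100 + i)
    K2 <- random_psd(n, ids = rownames(K1))
    hy <- hybrid_kernels(K1, K2)
    P <- K1 %*% K2
    expect_lt(max(abs(hy$CC + hy$PP - (P + t(P)))), 1e-10)
    expect_equal(unclass(hy$CC), t(unclass(hy$CC)), ignore_attr = TRUE)
    expect_equal(unclass(hy$PP), t(unclass(hy$PP)), ignore_attr = TRUE)
  }
})

test_that("commuting PSD inputs give an already-PSD product; repair is a no-op", {
  K1 <- random_psd(8, seed = 42)
  K2 <- K1 %*% K1 / max_eig(K1)   # polynomial of K1: commutes, PSD
  dimnames(K2) <- dimnames(K1)
  P <- K1 %*% K2
  expect_lt(max(abs(P - t(P))), 1e-10)
  expect_gte(min_eig(P), -1e-10 * max_eig(P))
  expect_equal(unclass(psd_repair(P)), unclass(P), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("hadamard_kernel is the entrywise product and keeps PSD", {
  K1 <- random_psd(6, seed = 8)
  ones <- matrix(1, 6, 6, dimnames = dimnames(K1))
  expect_equal(unclass(hadamard_kernel(K1, ones)), unclass(K1),
               ignore_attr = TRUE)
  K2 <- random_psd(6, ids = rownames(K1))
  H <- hadamard_kernel(K1, K2)
  expect_equal(unclass(H), unclass(K1) * unclass(K2), ignore_attr = TRUE)
  expect_gte(min_eig(H), -1e-10 * max_eig(H))
})

test_that("scale_kernel normalizes the mean diagonal and preserves shape", {
  I3 <- diag(3)
  expect_equal(unclass(scale_kernel(2 * I3)), I3, ignore_attr = TRUE)
  K <- random_psd(7, seed = 3)
  S <- scale_kernel(K)
  expect_equal(mean(diag(S)), 1, tolerance = 1e-12)
  expect_equal(unclass(scale_kernel(S)), unclass(S), ignore_attr = TRUE)
  # proportionality: eigenvector structure preserved
  expect_equal(unclass(S) * mean(diag(K)), unclass(K), ignore_attr = TRUE)
  expect_error(scale_kernel(-I3), "not positive")
})

test_that("psd_repair clips negative eigenvalues and nothing else", {
  K <- random_psd(6, seed = 19)
  expect_equal(unclass(psd_repair(K)), unclass(K), tolerance = 1e-10,
               ignore_attr = TRUE)

  K2 <- matrix(c(1, 2, 2, 1), 2, 2)  # eigenvalues 3 and -1
  R <- psd_repair(K2)
  expect_equal(unclass(R), matrix(1.5, 2, 2), tolerance = 1e-12,
               ignore_attr = TRUE)

  asym <- matrix(c(1, 2, 0, 1), 2, 2)
  expect_error(psd_repair(asym), "asymmetric")

  for (i in 1:10) {
    A <- matrix(rnorm(25), 5, 5)
    S <- (A + t(A)) / 2
    R <- psd_repair(S)
    expect_gte(min_eig(R), -1e-8 * max_eig(R))
  }
})
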