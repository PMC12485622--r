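# Kernel construction: per-layer linear and Gaussian kernels, the VanRaden
# genomic relationship matrix, hybrid upper/lower-triangle interaction
# kernels, Hadamard products, scaling and PSD repair.
#
# A kernel is an n x n symmetric numeric matrix with line IDs as dimnames
# and a "recipe" attribute recording how it was built; Gaussian kernels also
# carry their "bandwidth".

.new_kernel <- function(values, recipe, bandwidth = NULL) {
  values <- (values + t(values)) / 2   # remove floating-point asymmetry
  attr(values, "recipe") <- recipe
  attr(values, "bandwidth") <- bandwidth
  values
}

.check_kernel_pair <- function(K1, K2) {
  if (!identical(dim(K1), dim(K2)))
    .stopf("kernel dimension mismatch: %dx%d vs %dx%d",
           nrow(K1), ncol(K1), nrow(K2), ncol(K2))
  if (!identical(rownames(K1), rownames(K2)))
    .stopf("kernels are indexed by different line IDs")
  invisible(NULL)
}

#' Linear kernel
#'
#' Cross-product similarity `K = X X' / p` from a standardized feature
#' matrix, the usual relationship matrix for transcriptomic or metabolomic
#' layers.
#'
#' @param X Standardized feature matrix (lines x features).
#' @param recipe Construction tag stored on the result.
#' @return Symmetric PSD kernel matrix.
#' @export
linear_kernel <- function(X, recipe = "linear") {
  p <- ncol(X)
  if (is.null(p) || p < 1L) .stopf("linear_kernel: no features")
  .new_kernel(tcrossprod(X) / p, recipe)
}

#' VanRaden genomic relationship matrix
#'
#' From biallelic marker dosages coded 0/1/2, centers by twice the allele
#' frequency and scales by `2 * sum(p_k (1 - p_k))`:
#' `K = Z Z' / (2 sum p (1 - p))` with `Z = M - 2p`.
#'
#' @param M Marker matrix with 0/1/2 dosage coding (fractional dosages from
#'   mean imputation are accepted).
#' @return Symmetric PSD genomic kernel.
#' @export
vanraden_kernel <- function(M) {
  if (anyNA(M)) .stopf("vanraden_kernel: impute missing genotypes first")
  if (any(M < 0 | M > 2))
    .stopf("vanraden_kernel: dosages must lie in [0, 2] (0/1/2 coding)")
  p <- colMeans(M) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) .stopf("vanraden_kernel: all markers monomorphic")
  Z <- sweep(M, 2, 2 * p, "-")
  .new_kernel(tcrossprod(Z) / denom, "vanraden")
}

#' Gaussian kernel with the median-squared-distance bandwidth
#'
#' `K_ij = exp(-d2_ij / sigma)` with `d2` the squared Euclidean distance
#' between rows and bandwidth `sigma = median(d2)` over the off-diagonal
#' pairs. The diagonal is exactly 1.
#'
#' @param X Standardized feature matrix.
#' @param recipe Construction tag.
#' @return Symmetric kernel with entries in (0, 1].
#' @export
gaussian_kernel <- function(X, recipe = "gaussian") {
  n <- nrow(X)
  if (n < 2L) .stopf("gaussian_kernel: need at least 2 lines")
  d2 <- as.matrix(stats::dist(X))^2
  sigma <- stats::median(d2[upper.tri(d2)])
  if (!is.finite(sigma) || sigma <= 0)
    .stopf("gaussian_kernel: median squared distance is 0 (degenerate bandwidth)")
  K <- exp(-d2 / sigma)
  diag(K) <- 1
  .new_kernel(K, recipe, bandwidth = sigma)
}

#' Hybrid interaction kernels from a kernel product
#'
#' Forms the product `P = K1 K2` (generally asymmetric) and symmetrizes its
#' triangles: `K_CC = UT + UT'` with UT the upper triangle of P including
#' the diagonal, and `K_PP = LT + LT'` with LT the strictly lower triangle.
#' With this diagonal convention `UT + LT = P` exactly, so
#' `K_CC + K_PP = P + P'` entrywise. The symmetrized triangles need not be
#' PSD; pass the results through [psd_repair()] before use as covariances.
#'
#' @param K1,K2 Kernels on the same lines in the same order.
#' @return List with elements `CC` and `PP`.
#' @export
hybrid_kernels <- function(K1, K2) {
  .check_kernel_pair(K1, K2)
  P <- K1 %*% K2
  UT <- P; UT[lower.tri(UT)] <- 0          # diagonal kept in UT
  LT <- P; LT[upper.tri(LT, diag = TRUE)] <- 0
  tag <- paste(attr(K1, "recipe"), attr(K2, "recipe"), sep = "*")
  list(CC = .new_kernel(UT + t(UT), paste0(tag, ":CC")),
       PP = .new_kernel(LT + t(LT), paste0(tag, ":PP")))
}

#' Hadamard (entrywise) product kernel
#'
#' The conventional kernel interaction term; PSD whenever both inputs are
#' PSD (Schur product theorem). Provided for comparison with the hybrid
#' triangle kernels.
#'
#' @param K1,K2 Kernels on the same lines in the same order.
#' @return Symmetric kernel matrix.
#' @export
hadamard_kernel <- function(K1, K2) {
  .check_kernel_pair(K1, K2)
  .new_kernel(K1 * K2,
              paste(attr(K1, "recipe"), attr(K2, "recipe"), sep = "o"))
}

#' Scale a kernel to mean diagonal 1
#'
#' Dividing by the mean diagonal puts variance components estimated against
#' different kernels on a comparable scale.
#'
#' @param K Kernel matrix with positive mean diagonal.
#' @return Scaled kernel.
#' @export
scale_kernel <- function(K) {
  md <- mean(diag(K))
  if (!is.finite(md) || md <= 0)
    .stopf("scale_kernel: mean diagonal %.3g is not positive", md)
  out <- K / md
  attr(out, "recipe") <- attr(K, "recipe")
  attr(out, "bandwidth") <- attr(K, "bandwidth")
  out
}

#' Repair a kernel to positive semi-definiteness
#'
#' Eigendecomposes a symmetric matrix, clips negative eigenvalues to zero
#' and reconstructs. The clipped mass (sum of |negative eigenvalues| over
#' the total absolute spectrum) is reported when `verbose = TRUE`.
#'
#' @param K Symmetric matrix.
#' @param tol Relative symmetry tolerance.
#' @param verbose Log the clipped spectral mass.
#' @return PSD kernel matrix.
#' @export
psd_repair <- function(K, tol = 1e-8, verbose = FALSE) {
  asym <- max(abs(K - t(K)))
  if (asym > tol * max(1, max(abs(K))))
    .stopf("psd_repair: input asymmetric (max |K - K'| = %.3g)", asym)
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  neg <- e$values < 0
  if (!any(neg)) return(K)
  clipped <- sum(abs(e$values[neg])) / sum(abs(e$values))
  .msg(sprintf("psd_repair: clipped %.3g of spectral mass (%d eigenvalues)",
               clipped, sum(neg)), verbose = verbose)
  vals <- pmax(e$values, 0)
  out <- e$vectors %*% (vals * t(e$vectors))
  dimnames(out) <- dimnames(K)
  out <- .new_kernel(out, attr(K, "recipe"), attr(K, "bandwidth"))
  attr(out, "clipped_mass") <- clipped
  out
}
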