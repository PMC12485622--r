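# Shared fixtures, built in code.

# Small linked multi-omics dataset for pipeline-level tests.
tiny_dataset <- function(n = 40, p_g = 120, p_t = 60, p_m = 30,
                         n_traits = 1, seed = 11, ...) {
  simulate_dataset(n_lines = n, p_markers = p_g, p_transcripts = p_t,
                   p_metabolites = p_m, n_traits = n_traits, seed = seed, ...)
}

# Random symmetric PSD kernel with unit-ish diagonal.
random_psd <- function(n, seed = NULL, ids = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(rnorm(n * (n + 2)), n, n + 2)
  K <- tcrossprod(X) / (n + 2)
  if (is.null(ids)) ids <- paste0("L", seq_len(n))
  dimnames(K) <- list(ids, ids)
  K
}

min_eig <- function(K) min(eigen((K + t(K)) / 2, symmetric = TRUE,
                                 only.values = TRUE)$values)
max_eig <- function(K) max(eigen((K + t(K)) / 2, symmetric = TRUE,
                                 only.values = TRUE)$values)

# Reduced MCMC budget for cheap pipeline tests (still >= 50 retained draws).
fast_mcmc <- list(n_iter = 800, burn_in = 200, thin = 2)
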