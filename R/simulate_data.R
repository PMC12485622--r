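# Synthetic multi-omics data generator with known variance structure.
#
# Emulates the statistical structure the kernel models assume: three omics
# layers whose features share genetic signal (transcript and metabolite
# features are partly linear in the markers), and phenotypes composed of
# per-term random effects drawn from kernel covariances plus i.i.d.
# Gaussian noise, with configurable variance fractions.

#' Simulate biallelic marker genotypes
#'
#' Marker `k` receives an allele frequency drawn uniformly from
#' `maf_range`; dosages are Binomial(2, q_k) per line. Markers that come
#' out monomorphic are redrawn (up to 20 attempts) and dropped if still
#' monomorphic.
#'
#' @param n_lines Number of lines.
#' @param p_markers Number of markers.
#' @param maf_range Allele-frequency range, within (0, 0.5].
#' @param seed RNG seed.
#' @return Genomic feature matrix with 0/1/2 entries.
#' @export
simulate_genotypes <- function(n_lines, p_markers, maf_range = c(0.05, 0.5),
                               seed = 1) {
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    .stopf("maf_range must satisfy 0 < low <= high <= 0.5")
  set.seed(seed)
  q <- stats::runif(p_markers, maf_range[1], maf_range[2])
  M <- matrix(stats::rbinom(n_lines * p_markers, 2, rep(q, each = n_lines)),
              n_lines, p_markers)
  for (attempt in seq_len(20)) {
    mono <- apply(M, 2, function(x) length(unique(x)) == 1L)
    if (!any(mono)) break
    M[, mono] <- stats::rbinom(n_lines * sum(mono), 2,
                               rep(q[mono], each = n_lines))
  }
  mono <- apply(M, 2, function(x) length(unique(x)) == 1L)
  if (any(mono)) M <- M[, !mono, drop = FALSE]
  feature_matrix(M, "genomic",
                 line_ids = sprintf("L%03d", seq_len(n_lines)),
                 feature_ids = sprintf("SNP%05d", seq_len(ncol(M))))
}

#' Simulate an omics layer partially regulated by genotype
#'
#' Each feature is `sqrt(genetic_prop)` times a standardized linear
#' combination of a random subset of standardized markers plus
#' `sqrt(1 - genetic_prop)` times independent standard-normal noise;
#' columns are standardized afterwards. `genetic_prop = 0` gives a layer
#' independent of genotype, `genetic_prop = 1` an exact linear readout.
#'
#' @param geno Genomic feature matrix (0/1/2).
#' @param p Number of features to generate.
#' @param genetic_prop Fraction of each feature's variance driven by
#'   genotype, in \[0, 1\].
#' @param layer Output layer label (`"transcriptomic"` or
#'   `"metabolomic"`).
#' @param n_qtl Markers influencing each feature.
#' @param seed RNG seed.
#' @return Standardized feature matrix.
#' @export
simulate_omics_layer <- function(geno, p, genetic_prop,
                                 layer = "transcriptomic", n_qtl = 50,
                                 seed = 1) {
  if (p < 1L) .stopf("simulate_omics_layer: p must be >= 1")
  if (genetic_prop < 0 || genetic_prop > 1)
    .stopf("genetic_prop must lie in [0, 1]")
  set.seed(seed)
  n <- nrow(geno)
  Z <- standardize_features(geno)
  n_qtl <- min(n_qtl, ncol(Z))
  W <- matrix(0, ncol(Z), p)
  for (j in seq_len(p)) {
    idx <- sample.int(ncol(Z), n_qtl)
    W[idx, j] <- stats::rnorm(n_qtl)
  }
  score <- Z %*% W
  score <- scale(score)                       # unit-variance genetic score
  noise <- matrix(stats::rnorm(n * p), n, p)
  X <- sqrt(genetic_prop) * score + sqrt(1 - genetic_prop) * noise
  X <- feature_matrix(X, layer, line_ids = rownames(geno),
                      feature_ids = sprintf("%s%05d",
                                            toupper(substr(layer, 1, 1)),
                                            seq_len(p)))
  standardize_features(X)
}

#' Simulate phenotypes with known kernel variance structure
#'
#' For each trait, draws one random effect per configured kernel term from
#' `N(0, f_k K_k)` (sampling in the eigenbasis of the scaled, repaired
#' kernel) and adds `N(0, residual)` noise; the phenotype is then centered
#' and scaled to unit variance (effects and noise are rescaled identically,
#' so stored effects + noise reproduce the phenotype exactly and the
#' variance fractions keep their meaning).
#'
#' @param dataset An `omics_dataset` with the layers the terms reference.
#' @param fractions Named nonnegative vector of variance fractions keyed by
#'   predictor-grammar terms (e.g. `c(gL = 0.3, tL = 0.2, mL = 0.1)`).
#' @param residual Residual variance fraction; fractions + residual must
#'   sum to 1.
#' @param n_traits Number of independent traits.
#' @param seed RNG seed.
#' @param mu Intercept before standardization.
#' @return List with `phenotypes` (phenotype feature matrix) and `truth`
#'   (fractions, residual, generating model, per-trait effect matrices and
#'   noise, standardization constants).
#' @export
simulate_phenotypes <- function(dataset, fractions, residual = NULL,
                                n_traits = 1, seed = 1, mu = 0) {
  if (is.null(names(fractions)) || any(names(fractions) == ""))
    .stopf("fractions must be named by predictor terms (gL, tL, ...)")
  if (any(fractions < 0)) .stopf("variance fractions must be nonnegative")
  if (is.null(residual)) residual <- 1 - sum(fractions)
  total <- sum(fractions) + residual
  if (residual < 0 || abs(total - 1) > 1e-12)
    .stopf("variance fractions (%.3f) + residual (%.3f) must sum to 1 with residual >= 0",
           sum(fractions), residual)
  spec <- get_model_spec(paste(names(fractions), collapse = "+"))
  base <- build_base_kernels(dataset, models = spec$predictor)
  kernels <- materialize_kernels(spec, base)
  factors <- lapply(kernels, eigen_prepare)

  set.seed(.substream(seed, "phenotypes"))
  n <- length(dataset$line_ids)
  Y <- matrix(NA_real_, n, n_traits,
              dimnames = list(dataset$line_ids,
                              sprintf("trait%d", seq_len(n_traits))))
  effects <- vector("list", n_traits)
  noise <- matrix(NA_real_, n, n_traits)
  mus <- numeric(n_traits)
  for (tr in seq_len(n_traits)) {
    U <- matrix(0, n, length(factors),
                dimnames = list(dataset$line_ids, names(kernels)))
    for (k in seq_along(factors)) {
      f <- factors[[k]]
      U[, k] <- f$vectors %*%
        (sqrt(fractions[k] * f$values) * stats::rnorm(f$rank))
    }
    e <- stats::rnorm(n, 0, sqrt(residual))
    y_raw <- mu + rowSums(U) + e
    m <- mean(y_raw); s <- stats::sd(y_raw)
    Y[, tr] <- (y_raw - m) / s
    effects[[tr]] <- U / s
    noise[, tr] <- e / s
    mus[tr] <- (mu - m) / s
  }
  match_id <- names(.MODEL_TABLE)[match(spec$predictor, .MODEL_TABLE)]
  truth <- list(fractions = fractions, residual = residual,
                generating_model = if (!is.na(match_id)) match_id else spec$predictor,
                predictor = spec$predictor,
                mu = mus, effects = effects, noise = noise, seed = seed)
  list(phenotypes = feature_matrix(Y, "phenotype"), truth = truth)
}

#' Simulate a full linked multi-omics dataset
#'
#' Generates genotypes, a transcriptomic and a metabolomic layer carrying
#' overlapping genetic signal, and phenotypes with configured kernel
#' variance fractions. Defaults mirror the smallest benchmark population at
#' desk scale: 210 lines, 1000 markers, 2000 transcripts, 500 metabolites,
#' with phenotypic variance split 0.3 / 0.2 / 0.1 across the genomic,
#' transcriptomic and metabolomic linear-kernel terms and 0.4 residual.
#'
#' @param n_lines,p_markers,p_transcripts,p_metabolites Dimensions.
#' @param maf_range Marker allele-frequency range.
#' @param genetic_prop_t,genetic_prop_m Fraction of transcript/metabolite
#'   variance driven by genotype.
#' @param fractions Named kernel-term variance fractions (see
#'   [simulate_phenotypes()]).
#' @param residual Residual fraction (default `1 - sum(fractions)`).
#' @param n_traits Number of traits.
#' @param seed Master RNG seed.
#' @param name Dataset label.
#' @param write_dir Optional directory: writes the four TSV matrices in the
#'   dialect [load_matrix()] reads plus a `truth.json` sidecar.
#' @return An `omics_dataset` with blocks `genomic`, `transcriptomic`,
#'   `metabolomic`, `phenotypes` and the generator `truth` attached as an
#'   attribute.
#' @export
simulate_dataset <- function(n_lines = 210, p_markers = 1000,
                             p_transcripts = 2000, p_metabolites = 500,
                             maf_range = c(0.05, 0.5),
                             genetic_prop_t = 0.5, genetic_prop_m = 0.5,
                             fractions = c(gL = 0.3, tL = 0.2, mL = 0.1),
                             residual = NULL, n_traits = 3, seed = 1,
                             name = "synthetic", write_dir = NULL) {
  geno <- simulate_genotypes(n_lines, p_markers, maf_range,
                             seed = .substream(seed, "geno"))
  trans <- simulate_omics_layer(geno, p_transcripts, genetic_prop_t,
                                layer = "transcriptomic",
                                seed = .substream(seed, "trans"))
  metab <- simulate_omics_layer(geno, p_metabolites, genetic_prop_m,
                                layer = "metabolomic",
                                seed = .substream(seed, "metab"))
  ds <- align_layers(list(genomic = geno, transcriptomic = trans,
                          metabolomic = metab), name = name)
  ph <- simulate_phenotypes(ds, fractions, residual = residual,
                            n_traits = n_traits, seed = seed)
  ds$phenotypes <- ph$phenotypes[ds$line_ids, , drop = FALSE]
  attr(ds$phenotypes, "layer") <- "phenotype"
  attr(ds, "truth") <- ph$truth
  if (!is.null(write_dir)) {
    dir.create(write_dir, recursive = TRUE, showWarnings = FALSE)
    write_matrix(ds$genomic, file.path(write_dir, "genomic.tsv"))
    write_matrix(ds$transcriptomic, file.path(write_dir, "transcriptomic.tsv"))
    write_matrix(ds$metabolomic, file.path(write_dir, "metabolomic.tsv"))
    write_matrix(ds$phenotypes, file.path(write_dir, "phenotypes.tsv"))
    jsonlite::write_json(
      list(fractions = as.list(ph$truth$fractions),
           residual = ph$truth$residual,
           generating_model = ph$truth$generating_model,
           predictor = ph$truth$predictor, seed = seed),
      file.path(write_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  ds
}
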