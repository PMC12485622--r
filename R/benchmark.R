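# Benchmark driver: load or simulate a dataset, build kernels, run the
# selected models over traits and partitions, and write summary tables.

#' Run the full multi-omics prediction benchmark
#'
#' Orchestrates the complete protocol from one configuration: obtain the
#' dataset (from per-layer TSV paths or the synthetic generator), build the
#' base kernels every requested model needs, then for each trait and model
#' run (1) a full-data fit with 2 chains for variance components,
#' heritability and the Gelman-Rubin gate, and (2) single-chain
#' cross-validation fits over random train/test partitions scored by APC
#' and NRMSE. Hybrid kernels are cached per dataset, and every (trait,
#' model, partition, chain) cell draws from its own RNG substream of the
#' master seed, so any subset of the grid reproduces the full run's
#' numbers.
#'
#' @param config Configuration list or path to a YAML file with the same
#'   structure. Recognized fields:
#'   \describe{
#'     \item{dataset}{Either `list(paths = list(genomic = ..., transcriptomic
#'       = ..., metabolomic = ..., phenotypes = ...), delimiter = "\t")` or
#'       `list(simulate = list(...))` with [simulate_dataset()] arguments.}
#'     \item{models}{Character vector of registry ids or predictor strings
#'       (default all 24).}
#'     \item{traits}{Trait names or indices (default: all columns).}
#'     \item{cv}{`list(fraction = 0.5, partitions = 20)`.}
#'     \item{mcmc}{[rkhs_fit()] arguments: `n_iter`, `burn_in`, `thin`,
#'       `prior_df`, `prior_R2`.}
#'     \item{seed}{Master seed.}
#'     \item{output_dir}{Where to write CSVs and the manifest (optional:
#'       when `NULL` nothing is written).}
#'   }
#' @param verbose Log progress.
#' @return List with `records` (long CV data frame), `heritability`
#'   (per-trait full-data records incl. max R-hat), `summary` (the
#'   [aggregate_results()] tables) and `dataset`.
#' @export
run_benchmark <- function(config, verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  models <- config$models %||% model_ids()
  cv_cfg <- config$cv %||% list()
  cv_fraction <- cv_cfg$fraction %||% 0.5
  cv_count <- cv_cfg$partitions %||% 20
  mcmc <- config$mcmc %||% list()

  # --- dataset -------------------------------------------------------------
  ds_cfg <- config$dataset %||% list(simulate = list())
  if (!is.null(ds_cfg$paths)) {
    delim <- ds_cfg$delimiter %||% "\t"
    blocks <- list()
    for (block in c("genomic", "transcriptomic", "metabolomic")) {
      if (!is.null(ds_cfg$paths[[block]]))
        blocks[[block]] <- load_matrix(ds_cfg$paths[[block]], block,
                                       delimiter = delim, verbose = verbose)
    }
    if (is.null(ds_cfg$paths$phenotypes))
      .stopf("dataset paths must include 'phenotypes'")
    blocks$phenotypes <- load_matrix(ds_cfg$paths$phenotypes, "phenotype",
                                     delimiter = delim, verbose = verbose)
    dataset <- align_layers(blocks, name = ds_cfg$name %||% "dataset",
                            verbose = verbose)
  } else {
    sim_args <- ds_cfg$simulate %||% list()
    if (is.null(sim_args$seed)) sim_args$seed <- .substream(seed, "simulate")
    dataset <- do.call(simulate_dataset, sim_args)
  }

  # fail fast if a requested model needs an absent layer
  layer_block <- c(g = "genomic", t = "transcriptomic", m = "metabolomic")
  specs <- lapply(models, get_model_spec)
  names(specs) <- vapply(specs, `[[`, "", "model_id")
  for (sp in specs) {
    layers <- unique(unlist(lapply(sp$terms, `[[`, "layers")))
    absent <- layers[vapply(layer_block[layers],
                            function(b) is.null(dataset[[b]]), TRUE)]
    if (length(absent))
      .stopf("model %s requires the %s layer, which is not in the dataset",
             sp$model_id, layer_block[absent][1])
  }

  traits <- config$traits %||% colnames(dataset$phenotypes)
  if (is.numeric(traits)) traits <- colnames(dataset$phenotypes)[traits]

  .msg(sprintf("benchmark: %d models x %d traits x %d partitions on '%s' (n = %d)",
               length(specs), length(traits), cv_count, dataset$name,
               length(dataset$line_ids)), verbose = verbose)

  base <- build_base_kernels(dataset, models = models)
  cache <- new.env(parent = emptyenv())
  n <- length(dataset$line_ids)
  partitions <- make_partitions(n, seed = .substream(seed, "partitions"),
                                fraction = cv_fraction, count = cv_count)

  records <- list(); herit <- list()
  for (trait in traits) {
    y <- dataset$phenotypes[, trait]
    y <- standardize_trait(y)
    for (mid in names(specs)) {
      kern <- materialize_kernels(specs[[mid]], base, cache = cache)
      cell <- function(...) .substream(seed, dataset$name, trait, mid, ...)
      res <- tryCatch({
        full <- do.call(rkhs_fit, c(list(y = y, kernels = kern,
                                         n_chains = 2, seed = cell("full")),
                                    mcmc))
        h <- heritability(full)
        max_rhat <- max(c(full$varcomp$rhat, full$resid_var[["rhat"]]),
                        na.rm = TRUE)
        cv <- do.call(cross_validate,
                      c(list(y = y, kernels = kern, partitions = partitions,
                             seed = cell("cv")), mcmc))
        list(cv = cv, h = h, max_rhat = max_rhat, failed = FALSE)
      }, error = function(e) {
        .warnf("cell (%s, %s) failed: %s", trait, mid, conditionMessage(e))
        list(failed = TRUE)
      })
      if (res$failed) next
      records[[paste(trait, mid)]] <- data.frame(
        dataset = dataset$name, trait = trait, model = mid, res$cv)
      herit[[paste(trait, mid)]] <- data.frame(
        dataset = dataset$name, trait = trait, model = mid,
        VP = res$h$VP, Ve = res$h$Ve, h2 = res$h$h2, max_rhat = res$max_rhat)
      .msg(sprintf("  %s %s: h2 = %.3f, mean APC = %.3f", trait, mid,
                   res$h$h2, mean(res$cv$apc, na.rm = TRUE)),
           verbose = verbose)
    }
  }
  records <- do.call(rbind, c(records, list(make.row.names = FALSE)))
  herit <- do.call(rbind, c(herit, list(make.row.names = FALSE)))
  summary <- aggregate_results(records, herit)

  out_dir <- config$output_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(records, file.path(out_dir, "cv_records.csv"),
                     row.names = FALSE)
    utils::write.csv(herit, file.path(out_dir, "heritability_records.csv"),
                     row.names = FALSE)
    utils::write.csv(summary$accuracy, file.path(out_dir, "accuracy_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(summary$heritability,
                     file.path(out_dir, "heritability_summary.csv"),
                     row.names = FALSE)
    manifest <- list(
      package_version = as.character(utils::packageVersion("kernomics")),
      seed = seed, models = models, traits = traits,
      cv = list(fraction = cv_fraction, partitions = cv_count),
      mcmc = mcmc, dataset = dataset$name, n_lines = n,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(records = records, heritability = herit, summary = summary,
       dataset = dataset)
}

#' Standardize one trait vector
#'
#' Z-scores a phenotype column (observed entries), the per-trait
#' normalization applied before model fitting.
#'
#' @param y Numeric vector.
#' @return Standardized vector.
#' @export
standardize_trait <- function(y) {
  obs <- !is.na(y)
  if (.is_constant(y[obs])) .stopf("trait is constant; cannot standardize")
  (y - mean(y[obs])) / stats::sd(y[obs])
}
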