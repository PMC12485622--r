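# Evaluation protocol: random 50/50 train/test partitions, Pearson
# correlation (APC) and range-normalized RMSE (NRMSE) on test sets,
# full-data heritability, and table-style aggregation.

#' Random train/test partitions
#'
#' Generates `count` independent uniform-random splits of `n` lines at the
#' given training fraction (default 50/50). Index lists are sorted, and the
#' same seed reproduces the same partitions.
#'
#' @param n Number of lines (>= 4).
#' @param seed RNG seed.
#' @param fraction Training fraction (default 0.5).
#' @param count Number of partitions (default 20).
#' @return Object of class `partition_set`: list with `n`, `fraction`,
#'   `seed` and `partitions` (each a list with sorted `train`, `test`).
#' @export
make_partitions <- function(n, seed, fraction = 0.5, count = 20) {
  if (n < 4L) .stopf("make_partitions: need n >= 4, got %d", n)
  if (fraction <= 0 || fraction >= 1) .stopf("fraction must be in (0, 1)")
  set.seed(seed)
  n_train <- floor(n * fraction)
  parts <- lapply(seq_len(count), function(i) {
    train <- sort(sample.int(n, n_train))
    list(train = train, test = setdiff(seq_len(n), train))
  })
  structure(list(n = n, fraction = fraction, count = count, seed = seed,
                 partitions = parts),
            class = "partition_set")
}

#' @export
print.partition_set <- function(x, ...) {
  cat(sprintf("%d random partitions of %d lines (train fraction %.2f, seed %d)\n",
              x$count, x$n, x$fraction, x$seed))
  invisible(x)
}

#' Pearson correlation between observed and predicted values
#'
#' The per-partition accuracy metric; averaged over partitions and traits
#' it is reported as APC. Returns `NA` with a warning when either vector is
#' constant (correlation undefined).
#'
#' @param observed,predicted Equal-length numeric vectors (length >= 3).
#' @return Correlation in \[-1, 1\], or `NA`.
#' @export
apc <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    .stopf("apc: length mismatch (%d vs %d)", length(observed), length(predicted))
  if (length(observed) < 3L) .stopf("apc: need at least 3 pairs")
  if (.is_constant(observed) || .is_constant(predicted)) {
    .warnf("apc: constant observed or predicted vector; returning NA")
    return(NA_real_)
  }
  stats::cor(observed, predicted)
}

#' Range-normalized root mean squared error
#'
#' `RMSE / (max(observed) - min(observed))` by default; `normalizer =
#' "mean"` divides by the observed mean instead. Range normalization is
#' scale-free: multiplying both vectors by a constant leaves it unchanged.
#'
#' @param observed,predicted Equal-length numeric vectors (length >= 2).
#' @param normalizer `"range"` (default) or `"mean"`.
#' @return Nonnegative error.
#' @export
nrmse <- function(observed, predicted, normalizer = c("range", "mean")) {
  normalizer <- match.arg(normalizer)
  if (length(observed) != length(predicted))
    .stopf("nrmse: length mismatch (%d vs %d)", length(observed), length(predicted))
  if (length(observed) < 2L) .stopf("nrmse: need at least 2 pairs")
  rmse <- sqrt(mean((observed - predicted)^2))
  denom <- switch(normalizer,
                  range = diff(range(observed)),
                  mean = mean(observed))
  if (!is.finite(denom) || denom == 0)
    .stopf("nrmse: zero %s of observed values", normalizer)
  rmse / denom
}

#' Heritability from a fitted model
#'
#' Sums the posterior-mean variance components of every kernel term into
#' `VP` and returns `h2 = VP / (VP + Ve)` with `Ve` the posterior-mean
#' residual variance. Intended for full-data (unmasked) fits.
#'
#' @param fit An `rkhs_fit`.
#' @return List with `VP`, `Ve` and `h2`.
#' @export
heritability <- function(fit) {
  stopifnot(inherits(fit, "rkhs_fit"))
  VP <- sum(fit$varcomp$mean)
  Ve <- fit$resid_var[["mean"]]
  list(VP = VP, Ve = Ve, h2 = VP / (VP + Ve))
}

#' Cross-validate one model on one trait
#'
#' For each partition, masks the test lines, fits the model on the training
#' half by [rkhs_fit()] (single chain), and scores the posterior-mean
#' predictions on the test half with [apc()] and [nrmse()].
#'
#' @param y Phenotype vector (no missing values).
#' @param kernels Named kernel list for the model (see
#'   [materialize_kernels()]).
#' @param partitions A `partition_set` from [make_partitions()].
#' @param seed Master seed for per-partition sampler substreams.
#' @param ... Passed to [rkhs_fit()] (MCMC budget, priors).
#' @return Data frame with columns `partition`, `apc`, `nrmse`.
#' @export
cross_validate <- function(y, kernels, partitions, seed = 1, ...) {
  stopifnot(inherits(partitions, "partition_set"))
  if (anyNA(y)) .stopf("cross_validate: phenotype has missing values")
  if (length(y) != partitions$n)
    .stopf("cross_validate: phenotype length %d != partition n %d",
           length(y), partitions$n)
  rows <- lapply(seq_len(partitions$count), function(p) {
    test <- partitions$partitions[[p]]$test
    fit <- rkhs_fit(y, kernels, mask = test,
                    seed = .substream(seed, "partition", p), ...)
    pred <- fit$predictions
    data.frame(partition = p,
               apc = apc(y[test], pred),
               nrmse = nrmse(y[test], pred))
  })
  do.call(rbind, rows)
}

#' Aggregate evaluation and heritability records
#'
#' Summarizes long-format records the way the benchmark tables report them:
#' per (dataset, model), APC and NRMSE are averaged over partitions within
#' trait and then over traits; heritability is the per-trait ratio
#' `VP/(VP+Ve)` averaged across traits (mean of ratios, not ratio of
#' means), alongside means/sds of `VP` and `Ve`.
#'
#' @param cv_records Data frame with columns `dataset`, `trait`, `model`,
#'   `partition`, `apc`, `nrmse` (missing APCs excluded from means).
#' @param herit_records Optional data frame with columns `dataset`,
#'   `trait`, `model`, `VP`, `Ve`, `h2`.
#' @return List with data frames `accuracy` (model, apc_mean, apc_sd,
#'   nrmse_mean, nrmse_sd per dataset) and `heritability` (model, VP_mean,
#'   VP_sd, Ve_mean, Ve_sd, h2_mean, h2_sd per dataset), the latter `NULL`
#'   when no heritability records are given.
#' @export
aggregate_results <- function(cv_records, herit_records = NULL) {
  stopifnot(nrow(cv_records) > 0)
  n_miss <- sum(is.na(cv_records$apc))
  if (n_miss > 0)
    .msg(sprintf("aggregate_results: %d record(s) with undefined APC excluded",
                 n_miss))
  # mean over partitions within trait, then over traits
  per_trait <- stats::aggregate(
    cbind(apc, nrmse) ~ dataset + model + trait, data = cv_records,
    FUN = mean, na.rm = TRUE, na.action = stats::na.pass)
  acc <- do.call(rbind, lapply(
    split(per_trait, per_trait[c("dataset", "model")], drop = TRUE),
    function(d) data.frame(
      dataset = d$dataset[1], model = d$model[1],
      apc_mean = mean(d$apc, na.rm = TRUE),
      apc_sd = stats::sd(d$apc),
      nrmse_mean = mean(d$nrmse, na.rm = TRUE),
      nrmse_sd = stats::sd(d$nrmse))))
  rownames(acc) <- NULL

  her <- NULL
  if (!is.null(herit_records) && nrow(herit_records) > 0) {
    her <- do.call(rbind, lapply(
      split(herit_records, herit_records[c("dataset", "model")], drop = TRUE),
      function(d) data.frame(
        dataset = d$dataset[1], model = d$model[1],
        VP_mean = mean(d$VP), VP_sd = stats::sd(d$VP),
        Ve_mean = mean(d$Ve), Ve_sd = stats::sd(d$Ve),
        h2_mean = mean(d$h2), h2_sd = stats::sd(d$h2))))
    rownames(her) <- NULL
  }
  list(accuracy = acc, heritability = her)
}
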