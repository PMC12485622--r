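# Reading, validation and preprocessing of per-layer feature matrices.
#
# A feature matrix is a plain numeric matrix: rows are lines (genotypes),
# columns are features, rownames carry the line IDs and colnames the feature
# IDs. The omics layer ("genomic", "transcriptomic", "metabolomic",
# "phenotype") is kept in the "layer" attribute.

.LAYERS <- c("genomic", "transcriptomic", "metabolomic", "phenotype")

#' Construct a feature matrix
#'
#' Validates and tags an n x p numeric matrix of per-line omics features.
#' Line IDs (rownames) and feature IDs (colnames) must be unique.
#'
#' @param values Numeric matrix, lines in rows and features in columns.
#'   Missing values are allowed before imputation.
#' @param layer One of `"genomic"`, `"transcriptomic"`, `"metabolomic"`,
#'   `"phenotype"`.
#' @param line_ids,feature_ids Optional identifier vectors overriding the
#'   dimnames of `values`.
#' @return The validated matrix with a `layer` attribute.
#' @export
feature_matrix <- function(values, layer, line_ids = NULL, feature_ids = NULL) {
  layer <- match.arg(layer, .LAYERS)
  values <- as.matrix(values)
  if (!is.numeric(values)) .stopf("feature matrix for layer '%s' must be numeric", layer)
  if (!is.null(line_ids)) rownames(values) <- line_ids
  if (!is.null(feature_ids)) colnames(values) <- feature_ids
  if (is.null(rownames(values))) rownames(values) <- paste0("L", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- paste0("F", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1]
    .stopf("duplicate line ID '%s' in %s matrix", dup, layer)
  }
  if (anyDuplicated(colnames(values))) {
    dup <- colnames(values)[duplicated(colnames(values))][1]
    .stopf("duplicate feature ID '%s' in %s matrix", dup, layer)
  }
  attr(values, "layer") <- layer
  values
}

#' Read a delimited feature matrix
#'
#' Reads a delimited text file (first column = line ID when the file has a
#' header) into a feature matrix. Empty cells and `"NA"` (case-insensitive,
#' or any token in `missing_tokens`) become missing values.
#'
#' @param path File path.
#' @param layer Omics layer label, see [feature_matrix()].
#' @param delimiter Field separator (default tab).
#' @param has_header Whether the file carries a header row and a leading
#'   line-ID column (default `TRUE`).
#' @param missing_tokens Character tokens treated as missing.
#' @param verbose Log parsed dimensions.
#' @return A feature matrix (see [feature_matrix()]).
#' @export
load_matrix <- function(path, layer, delimiter = "\t", has_header = TRUE,
                        missing_tokens = c("", "NA"), verbose = FALSE) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  raw <- utils::read.table(path, sep = delimiter, header = has_header,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "", stringsAsFactors = FALSE)
  if (has_header) {
    ids <- raw[[1]]
    raw <- raw[, -1, drop = FALSE]
  } else {
    ids <- paste0("L", seq_len(nrow(raw)))
  }
  if (anyDuplicated(ids)) {
    .stopf("duplicate line ID '%s' in %s", ids[duplicated(ids)][1], path)
  }
  vals <- matrix(NA_real_, nrow(raw), ncol(raw),
                 dimnames = list(ids, colnames(raw)))
  tokens <- toupper(missing_tokens)
  for (j in seq_len(ncol(raw))) {
    cell <- trimws(raw[[j]])
    miss <- toupper(cell) %in% tokens
    num <- suppressWarnings(as.numeric(cell))
    bad <- !miss & is.na(num)
    if (any(bad)) {
      i <- which(bad)[1]
      .stopf("non-numeric value '%s' at row %d (line '%s'), column '%s' of %s",
             cell[i], i, ids[i], colnames(raw)[j], path)
    }
    num[miss] <- NA_real_
    vals[, j] <- num
  }
  .msg(sprintf("loaded %s matrix: %d lines x %d features (%s)",
               layer, nrow(vals), ncol(vals), path), verbose = verbose)
  feature_matrix(vals, layer)
}

#' Write a feature matrix in the dialect [load_matrix()] reads
#'
#' @param X Feature matrix.
#' @param path Output path.
#' @param delimiter Field separator.
#' @export
write_matrix <- function(X, path, delimiter = "\t") {
  df <- data.frame(line_id = rownames(X), X, check.names = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Column-mean imputation
#'
#' Replaces each missing entry by the mean of the observed entries in its
#' column; observed entries are unchanged.
#'
#' @param X Feature matrix.
#' @return Imputed feature matrix.
#' @export
mean_impute <- function(X) {
  if (!anyNA(X)) return(X)
  all_missing <- colSums(!is.na(X)) == 0L
  if (any(all_missing)) {
    .stopf("column '%s' has no observed values; drop it before imputation",
           colnames(X)[all_missing][1])
  }
  means <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X), arr.ind = TRUE)
  X[idx] <- means[idx[, 2]]
  X
}

#' Z-score standardization of features
#'
#' Centers each column to mean 0 and scales to sample standard deviation 1
#' (n - 1 denominator). Zero-variance columns are dropped with a warning.
#' Run after [mean_impute()]; missing values are an error.
#'
#' @param X Feature matrix without missing values.
#' @return The standardized feature matrix, possibly with fewer columns.
#' @export
standardize_features <- function(X) {
  if (anyNA(X)) .stopf("missing values present; run mean_impute() first")
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  if (!any(keep)) .stopf("all %d columns have zero variance", ncol(X))
  if (any(!keep)) {
    .warnf("dropping %d zero-variance feature(s) (e.g. '%s')",
           sum(!keep), colnames(X)[!keep][1])
    X <- X[, keep, drop = FALSE]
    sds <- sds[keep]
  }
  out <- sweep(sweep(X, 2, colMeans(X), "-"), 2, sds, "/")
  attr(out, "layer") <- attr(X, "layer")
  out
}

#' Assemble a multi-omics dataset on a shared line ordering
#'
#' Restricts the supplied layer matrices to the intersection of their line
#' IDs and reorders every block to one canonical (lexicographically sorted)
#' order so that all kernels and phenotypes share row order.
#'
#' @param blocks Named list of feature matrices; names among
#'   `genomic`, `transcriptomic`, `metabolomic`, `phenotypes`.
#' @param name Dataset label.
#' @param verbose Log dropped-line counts.
#' @return An object of class `omics_dataset`: the aligned blocks plus
#'   `name` and `line_ids`.
#' @export
align_layers <- function(blocks, name = "dataset", verbose = FALSE) {
  stopifnot(is.list(blocks), length(blocks) >= 1)
  ids <- Reduce(intersect, lapply(blocks, rownames))
  if (length(ids) == 0L) .stopf("no line IDs shared by all layers")
  ids <- sort(ids)
  dropped <- sum(vapply(blocks, nrow, 1L)) - length(ids) * length(blocks)
  if (dropped > 0)
    .msg(sprintf("align_layers: dropped %d non-shared line rows", dropped),
         verbose = verbose)
  out <- lapply(blocks, function(b) {
    r <- b[ids, , drop = FALSE]
    attr(r, "layer") <- attr(b, "layer")
    r
  })
  out$name <- name
  out$line_ids <- ids
  class(out) <- "omics_dataset"
  if (length(ids) < 4L)
    .stopf("dataset has %d shared lines; at least 4 required", length(ids))
  out
}

#' @export
print.omics_dataset <- function(x, ...) {
  cat("Multi-omics dataset:", x$name, "\n")
  cat("  lines:", length(x$line_ids), "\n")
  for (b in intersect(c("genomic", "transcriptomic", "metabolomic", "phenotypes"),
                      names(x))) {
    cat(sprintf("  %-14s %d features\n", b, ncol(x[[b]])))
  }
  invisible(x)
}
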