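# Registry of the 24 standard multi-omics predictors and the textual
# predictor grammar.
#
# A predictor is a "+"-joined list of terms. A main-effect term is a layer
# letter (g/t/m) plus a kernel-kind subscript (L = linear, G = Gaussian),
# e.g. "gL", "tG". An interaction term names two layer/kind pairs plus a
# combo suffix: "CC" (symmetrized upper triangle of the kernel product,
# diagonal included) or "PP" (symmetrized strictly lower triangle), e.g.
# "gLtLCC", "tGmGPP".

.MODEL_TABLE <- c(
  M1  = "gL",
  M2  = "tL",
  M3  = "mL",
  M4  = "gL+tL+mL",
  M5  = "gL+tL+mL+gLtLCC+gLtLPP",
  M6  = "gL+tL+mL+gLmLCC+gLmLPP",
  M7  = "gL+tL+mL+tLmLCC+tLmLPP",
  M8  = "gL+tL+mL+gLtLCC+gLtLPP+gLmLCC+gLmLPP",
  M9  = "gL+tL+mL+gLtLCC+gLtLPP+tLmLCC+tLmLPP",
  M10 = "gL+tL+mL+gLmLCC+gLmLPP+tLmLCC+tLmLPP",
  M11 = "gL+tL+mL+gLtLCC+gLtLPP+gLmLCC+gLmLPP+tLmLCC+tLmLPP",
  M12 = "gG",
  M13 = "tG",
  M14 = "mG",
  M15 = "gG+tG+mG",
  M16 = "gG+tG+mG+gGtGCC+gGtGPP",
  M17 = "gG+tG+mG+gGmGCC+gGmGPP",
  M18 = "gG+tG+mG+tGmGCC+tGmGPP",
  M19 = "gG+tG+mG+gGtGCC+gGtGPP+gGmGCC+gGmGPP",
  M20 = "gG+tG+mG+gGtGCC+gGtGPP+tGmGCC+tGmGPP",
  M21 = "gG+tG+mG+gGmGCC+gGmGPP+tGmGCC+tGmGPP",
  M22 = "gG+tG+mG+gGtGCC+gGtGPP+gGmGCC+gGmGPP+tGmGCC+tGmGPP",
  M23 = "gL+tL+mL+gG+tG+mG",
  M24 = "gL+tL+mL+gG+tG+mG+gGtGCC+gGtGPP+gGmGCC+gGmGPP+tGmGCC+tGmGPP"
)

#' Model identifiers of the standard registry
#'
#' @return Character vector `"M1"` ... `"M24"`.
#' @export
model_ids <- function() names(.MODEL_TABLE)

#' Parse one predictor term
#'
#' @param term Term string in the predictor grammar (case-sensitive), e.g.
#'   `"gL"` or `"tGmGPP"`.
#' @return List with `layers` (one or two of g/t/m), `kinds`
#'   (`"linear"`/`"gaussian"` per layer), `combo` (`"main"`, `"CC"` or
#'   `"PP"`), and the canonical `label`.
#' @export
parse_term <- function(term) {
  kind_of <- c(L = "linear", G = "gaussian")
  if (grepl("^[gtm][LG]$", term)) {
    return(list(layers = substr(term, 1, 1),
                kinds = unname(kind_of[substr(term, 2, 2)]),
                combo = "main", label = term))
  }
  m <- regmatches(term, regexec("^([gtm])([LG])([gtm])([LG])(CC|PP)$", term))[[1]]
  if (length(m) == 0L)
    .stopf("cannot parse predictor term '%s'", term)
  if (m[2] == m[4])
    .stopf("interaction term '%s' repeats layer '%s'", term, m[2])
  list(layers = c(m[2], m[4]),
       kinds = unname(kind_of[c(m[3], m[5])]),
       combo = m[6], label = term)
}

#' Retrieve or parse a model specification
#'
#' Accepts a registry identifier (`"M1"`..`"M24"`) or a custom predictor
#' string in the same grammar (terms joined by `"+"`).
#'
#' @param model Model id or predictor string.
#' @return List of class `model_spec` with `model_id`, `predictor`,
#'   `term_labels` and parsed `terms`.
#' @export
get_model_spec <- function(model) {
  if (model %in% names(.MODEL_TABLE)) {
    predictor <- .MODEL_TABLE[[model]]
    id <- model
  } else if (grepl("+", model, fixed = TRUE) || grepl("^[gtm][LG]", model)) {
    predictor <- model
    id <- model
  } else {
    .stopf("unknown model '%s'; valid ids: %s", model,
           paste(names(.MODEL_TABLE), collapse = ", "))
  }
  labels <- strsplit(predictor, "+", fixed = TRUE)[[1]]
  if (anyDuplicated(labels))
    .stopf("model '%s' repeats term '%s'", id, labels[duplicated(labels)][1])
  terms <- lapply(labels, parse_term)
  structure(list(model_id = id, predictor = predictor,
                 term_labels = labels, terms = terms),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Model", x$model_id, ":", x$predictor, "\n")
  cat(" ", length(x$terms), "kernel term(s)\n")
  invisible(x)
}

#' Base kernel names a model needs
#'
#' @param spec A `model_spec`.
#' @return Character vector of base kernel labels (e.g. `"gL"`, `"tG"`).
#' @export
required_base_kernels <- function(spec) {
  kind_letter <- c(linear = "L", gaussian = "G")
  unique(unlist(lapply(spec$terms, function(tm) {
    paste0(tm$layers, kind_letter[tm$kinds])
  })))
}

#' Materialize the kernel list for a model
#'
#' Maps main-effect terms to their base kernels and interaction terms to
#' the CC/PP hybrid of the two named base kernels ([hybrid_kernels()]),
#' followed by PSD repair and mean-diagonal scaling. Hybrid pairs are
#' computed once and memoized in `cache` so that every model sharing a pair
#' reuses the identical matrices.
#'
#' @param spec A `model_spec` (or model id/predictor string).
#' @param base Named list of base kernels, names as in
#'   [required_base_kernels()] (`gL`, `tL`, `mL`, `gG`, `tG`, `mG`).
#' @param cache Optional environment memoizing hybrid kernels across calls.
#' @return Named list of kernel matrices, one per term, in predictor order.
#' @export
materialize_kernels <- function(spec, base, cache = NULL) {
  if (is.character(spec)) spec <- get_model_spec(spec)
  kind_letter <- c(linear = "L", gaussian = "G")
  need <- required_base_kernels(spec)
  missing <- setdiff(need, names(base))
  if (length(missing))
    .stopf("model '%s' needs base kernel(s) %s not provided",
           spec$model_id, paste(missing, collapse = ", "))
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  out <- vector("list", length(spec$terms))
  names(out) <- spec$term_labels
  for (i in seq_along(spec$terms)) {
    tm <- spec$terms[[i]]
    if (tm$combo == "main") {
      out[[i]] <- base[[paste0(tm$layers, kind_letter[tm$kinds])]]
    } else {
      b1 <- paste0(tm$layers[1], kind_letter[tm$kinds[1]])
      b2 <- paste0(tm$layers[2], kind_letter[tm$kinds[2]])
      key <- paste(b1, b2, sep = "x")
      if (is.null(cache[[key]])) {
        hy <- hybrid_kernels(base[[b1]], base[[b2]])
        cache[[key]] <- lapply(hy, function(K) scale_kernel(psd_repair(K)))
      }
      out[[i]] <- cache[[key]][[tm$combo]]
    }
  }
  out
}

#' Build the base kernels of a dataset
#'
#' Computes the per-layer base kernels a set of models needs: `gL` is the
#' VanRaden genomic relationship from 0/1/2 marker dosages, `tL`/`mL` are
#' linear kernels on standardized features, and `gG`/`tG`/`mG` are Gaussian
#' kernels (markers standardized before the distance computation). All base
#' kernels are scaled to mean diagonal 1.
#'
#' @param dataset An `omics_dataset` with blocks `genomic`,
#'   `transcriptomic`, `metabolomic` (phenotypes ignored here).
#' @param which Base kernel names to build; default: those required by
#'   `models`.
#' @param models Model ids/predictors whose base kernels to build (default
#'   all 24).
#' @return Named list of kernels.
#' @export
build_base_kernels <- function(dataset, which = NULL, models = model_ids()) {
  if (is.null(which)) {
    which <- unique(unlist(lapply(models, function(m)
      required_base_kernels(get_model_spec(m)))))
  }
  layer_block <- c(g = "genomic", t = "transcriptomic", m = "metabolomic")
  out <- list()
  std_cache <- list()
  std <- function(block) {
    if (is.null(std_cache[[block]])) {
      std_cache[[block]] <<- standardize_features(mean_impute(dataset[[block]]))
    }
    std_cache[[block]]
  }
  for (nm in which) {
    layer <- substr(nm, 1, 1)
    kind <- substr(nm, 2, 2)
    block <- layer_block[[layer]]
    if (is.null(dataset[[block]]))
      .stopf("dataset '%s' has no %s layer (needed for kernel %s)",
             dataset$name, block, nm)
    K <- if (kind == "L" && layer == "g") {
      vanraden_kernel(mean_impute(dataset[[block]]))
    } else if (kind == "L") {
      linear_kernel(std(block), recipe = paste0(block, ":linear"))
    } else {
      gaussian_kernel(std(block), recipe = paste0(block, ":gaussian"))
    }
    out[[nm]] <- scale_kernel(K)
  }
  out
}
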