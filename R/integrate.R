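#' Pool best-model variables across layers
#'
#' Builds the meta-dimensional input: the union, across layers, of each best
#' model's variables, each column copied unchanged from its source layer and
#' tagged with the layer of origin. Features are qualified as
#' \code{layer:feature} so same-named features of different layers stay
#' distinct.
#'
#' @param best_models named list (layer -> \code{genn_network}); an empty or
#'   \code{NULL} entry contributes nothing.
#' @param datasets named list (layer -> \code{\link{omics_dataset}}), sample-
#'   aligned.
#' @return An \code{\link{omics_dataset}} with layer \code{"integrated"} and
#'   attribute \code{"layer_of"} mapping pooled columns to source layers.
#' @export
pool_best_variables <- function(best_models, datasets) {
  stopifnot(length(datasets) >= 1L,
            all(names(best_models) %in% names(datasets)))
  cols <- list(); layer_of <- character(0); nms <- character(0)
  for (lay in names(best_models)) {
    m <- best_models[[lay]]
    if (is.null(m)) next
    vars <- unique(model_variables(m))
    d <- datasets[[lay]]
    miss <- setdiff(vars, colnames(d$x))
    if (length(miss) > 0L)
      stop("best-model variable(s) missing from layer '", lay, "': ",
           paste(miss, collapse = ", "))
    for (v in vars) {
      cols[[length(cols) + 1L]] <- d$x[, v]
      nms <- c(nms, paste0(lay, ":", v))
      layer_of <- c(layer_of, lay)
    }
  }
  if (length(cols) == 0L) stop("no variables pooled (all best models empty)")
  x <- do.call(cbind, cols)
  dimnames(x) <- list(rownames(datasets[[1L]]$x), nms)
  out <- omics_dataset(x, datasets[[1L]]$y, layer = "integrated")
  attr(out, "layer_of") <- stats::setNames(layer_of, nms)
  out
}

# Union of full layers (joint meta-dimensional search space).
pool_layers <- function(datasets) {
  nms <- unlist(lapply(names(datasets), function(lay)
    paste0(lay, ":", colnames(datasets[[lay]]$x))))
  x <- do.call(cbind, lapply(datasets, function(d) d$x))
  dimnames(x) <- list(rownames(datasets[[1L]]$x), nms)
  layer_of <- stats::setNames(
    rep(names(datasets), vapply(datasets, function(d) ncol(d$x), 0L)), nms)
  out <- omics_dataset(x, datasets[[1L]]$y, layer = "integrated")
  attr(out, "layer_of") <- layer_of
  out
}

#' Meta-dimensional integration of omics layers
#'
#' Runs the integration stage: single-layer cross-validated searches per
#' layer, pooling of variables into one combined dataset, a cross-validated
#' search on the pooled data, and paired comparison (exact two-sided Wilcoxon
#' signed-rank over the shared folds' test balanced accuracies) of the
#' integrated model against each single-layer model. One fold assignment,
#' derived from \code{seed}, is shared by every run so the comparisons are
#' paired.
#'
#' Pooling modes: \code{"best"} pools the variables of each layer's selected
#' best model (the published design); \code{"folds"} pools the variables of
#' all fold-best models, hedging against signals missed by the single best;
#' \code{"layers"} searches the union of the layers' features jointly — the
#' mode designed for cross-layer interactions whose components have no
#' marginal effect within their own layer and therefore cannot survive
#' per-layer model selection.
#'
#' @param datasets named list of sample-aligned \code{\link{omics_dataset}}s.
#' @param grammar a \code{genn_grammar}.
#' @param control \code{\link{genn_control}} for the integrated search.
#' @param layer_control \code{genn_control} for the single-layer searches
#'   (defaults to \code{control}).
#' @param pool pooling mode, see Details.
#' @param filter optional filter spec passed to \code{\link{run_cv}} for the
#'   single-layer runs.
#' @param k folds.
#' @param seed integer seed.
#' @return Object of class \code{genn_integration}: \code{final_model},
#'   \code{fold_accuracies}, \code{consistency}, \code{comparisons}
#'   (data.frame layer/p_value), \code{layer_fits}, \code{integrated_fit},
#'   \code{pooled} dataset.
#' @export
genn_integrate <- function(datasets, grammar = genn_grammar(),
                           control = genn_control(),
                           layer_control = control,
                           pool = c("best", "folds", "layers"),
                           filter = NULL, k = 5L, seed = 1L) {
  pool <- match.arg(pool)
  stopifnot(length(datasets) >= 1L, !is.null(names(datasets)))
  datasets <- align_samples(datasets)
  names(datasets) <- vapply(datasets, `[[`, "", "layer")
  y <- datasets[[1L]]$y
  ids <- rownames(datasets[[1L]]$x)
  folds <- split_folds(ids, y, k = k, seed = seed)

  layer_fits <- lapply(seq_along(datasets), function(i) {
    d <- datasets[[i]]
    run_cv(d$x, y, grammar = grammar, control = layer_control,
           folds = folds, seed = derive_seed(seed, 3000L + i),
           filter = filter, layers = rep(d$layer, ncol(d$x)))
  })
  names(layer_fits) <- names(datasets)

  pooled <- switch(pool,
    best = pool_best_variables(lapply(layer_fits, `[[`, "selected_model"),
                               datasets),
    folds = {
      fold_models <- lapply(layer_fits, function(fit) {
        vars <- unique(unlist(lapply(fit$per_fold, function(pf)
          model_variables(pf$model))))
        synth_union_model(vars)
      })
      pool_best_variables(fold_models, datasets)
    },
    layers = pool_layers(datasets))

  layer_of <- attr(pooled, "layer_of")
  integrated <- run_cv(pooled$x, y, grammar = grammar, control = control,
                       folds = folds, seed = derive_seed(seed, 4000L),
                       layers = as.character(layer_of))
  int_ba <- vapply(integrated$per_fold, `[[`, 0, "test_ba")
  comparisons <- data.frame(
    layer = names(layer_fits),
    p_value = vapply(layer_fits, function(fit) {
      wilcoxon_exact(int_ba, vapply(fit$per_fold, `[[`, 0, "test_ba"))$p_value
    }, 0),
    row.names = NULL)

  structure(list(final_model = integrated$selected_model,
                 fold_accuracies = int_ba,
                 consistency = integrated$consistency,
                 comparisons = comparisons,
                 layer_fits = layer_fits,
                 integrated_fit = integrated,
                 pooled = pooled,
                 folds = folds, seed = seed),
            class = "genn_integration")
}

# A stand-in "model" carrying only a variable set, for pooling mode "folds".
synth_union_model <- function(vars) {
  if (length(vars) == 0L) return(NULL)
  # build a trivial network over the first variable, then override variables
  m <- parse_network("PADD(1.0*V1,1.0*V1)")
  m$var_names <- vars
  m$variables <- seq_along(vars)
  m
}

#' @export
print.genn_integration <- function(x, ...) {
  cat("Meta-dimensional integration over",
      length(x$layer_fits), "layers\n")
  for (lay in names(x$layer_fits)) {
    ba <- vapply(x$layer_fits[[lay]]$per_fold, `[[`, 0, "test_ba")
    cat(sprintf("  %-12s mean test balanced accuracy %.4f\n", lay, mean(ba)))
  }
  cat(sprintf("  %-12s mean test balanced accuracy %.4f\n", "integrated",
              mean(x$fold_accuracies)))
  cat("Final model:", format(x$final_model, use_names = TRUE), "\n")
  cat("Paired comparisons (exact two-sided Wilcoxon signed-rank):\n")
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}

#' @export
summary.genn_integration <- function(object, ...) {
  vars <- model_variables(object$final_model)
  layer_of <- attr(object$pooled, "layer_of")
  out <- list(
    final = format(object$final_model, use_names = TRUE),
    variables = data.frame(
      variable = vars,
      layer = as.character(layer_of[vars]),
      consistency = as.integer(object$consistency[vars]),
      row.names = NULL),
    fold_accuracies = object$fold_accuracies,
    comparisons = object$comparisons)
  class(out) <- "summary.genn_integration"
  out
}

#' @export
print.summary.genn_integration <- function(x, ...) {
  cat("Final meta-dimensional model:", x$final, "\n\nVariables:\n")
  print(x$variables, row.names = FALSE)
  cat("\nFold test balanced accuracies:",
      paste(sprintf("%.3f", x$fold_accuracies), collapse = " "), "\n")
  cat("\nComparisons:\n")
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}
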