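#' Stratified k-fold assignment
#'
#' Samples of each class are shuffled and dealt into folds so that fold sizes
#' differ by at most one and each fold's class proportions are within one
#' sample of the overall proportions. With 258 samples (110 + 148) and
#' \code{k = 5} this yields fold sizes 52, 52, 52, 51, 51 with 22
#' class-1 samples in every fold.
#'
#' @param sample_ids character or integer identifiers.
#' @param labels classes (0/1), one per sample.
#' @param k number of folds (>= 2); every class must have at least \code{k}
#'   samples.
#' @param seed integer seed.
#' @return Integer vector of fold indices in \code{1..k}, named by sample id.
#' @export
split_folds <- function(sample_ids, labels, k = 5L, seed = 1L) {
  labels <- as_binary(labels)
  stopifnot(length(sample_ids) == length(labels), k >= 2L,
            anyDuplicated(sample_ids) == 0L)
  counts <- table(factor(labels, levels = c(0L, 1L)))
  if (any(counts < k))
    stop("every class needs at least k samples (class sizes: ",
         paste(counts, collapse = ", "), ")")
  fold <- integer(length(labels))
  offset <- 0L   # rotates the folds receiving remainder samples across
                 # classes so overall fold sizes stay within one sample
  with_seed(seed, {
    for (cl in c(1L, 0L)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      nc <- length(idx)
      sizes <- rep(nc %/% k, k)
      extra <- nc %% k
      if (extra > 0L) {
        bump <- ((offset + seq_len(extra) - 1L) %% k) + 1L
        sizes[bump] <- sizes[bump] + 1L
        offset <- (offset + extra) %% k
      }
      fold[idx] <- rep(seq_len(k), times = sizes)
    }
  })
  stats::setNames(fold, sample_ids)
}

#' Cross-validated network search
#'
#' Runs the full protocol: for each of \code{k} folds, a search
#' (\code{\link{run_search}}) on the other \code{k - 1} folds' samples, with
#' the held-out fold scored by the fold's best model. When \code{filter} is
#' given, the frequency-based filtering stage is re-run inside every training
#' fold (so held-out samples never influence variable retention) and the
#' fold's search sees only the retained columns. Features are z-scored using
#' training-fold statistics.
#'
#' @param x samples x features matrix with column names.
#' @param y classes (0/1), one per row of \code{x}.
#' @param grammar a \code{genn_grammar}.
#' @param control a \code{\link{genn_control}} for the modelling search.
#' @param k number of folds.
#' @param seed integer seed (drives fold assignment, filtering, and search).
#' @param folds optional precomputed fold assignment (from
#'   \code{\link{split_folds}}); lets several runs share one assignment for
#'   paired comparison.
#' @param filter \code{NULL} (no filtering) or a list with \code{fraction}
#'   (top fraction of variables kept) and optionally \code{control} (a
#'   \code{genn_control} for the filtering search; default
#'   \code{genn_control(demes = 10, pop_size = 500, generations = 20,
#'   migrations = 1)}).
#' @param layers optional per-column layer names.
#' @param standardize z-score features with training-fold statistics
#'   (default TRUE).
#' @return Object of class \code{genn_cv}: \code{per_fold} (model, train/test
#'   balanced accuracy, expression), \code{selected_model},
#'   \code{consistency}, \code{folds}, \code{filter_logs}.
#' @export
run_cv <- function(x, y, grammar = genn_grammar(), control = genn_control(),
                   k = 5L, seed = 1L, folds = NULL, filter = NULL,
                   layers = NULL, standardize = TRUE) {
  x <- as_feature_matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  y <- as_binary(y)
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  if (is.null(folds)) folds <- split_folds(ids, y, k = k, seed = seed)
  k <- max(folds)
  if (!is.null(filter)) {
    if (is.numeric(filter)) filter <- list(fraction = filter)
    if (is.null(filter$control))
      filter$control <- genn_control(demes = 10L, pop_size = 500L,
                                     generations = 20L, migrations = 1L)
  }
  per_fold <- vector("list", k)
  filter_logs <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f
    xtr <- x[tr, , drop = FALSE]; ytr <- y[tr]
    xte <- x[!tr, , drop = FALSE]; yte <- y[!tr]
    if (standardize) {
      st <- standardize_stats(xtr)
      xtr <- apply_standardize(xtr, st)
      xte <- apply_standardize(xte, st)
    }
    lay <- layers
    if (!is.null(filter)) {
      fs <- run_search(xtr, ytr, grammar = grammar, control = filter$control,
                       seed = derive_seed(seed, 500L + f), layers = layers)
      tab <- variable_frequency(log_variable_sets(fs),
                                all_variables = colnames(x), layers = layers)
      keep <- apply_threshold(tab, filter$fraction)
      filter_logs[[f]] <- tab
      xtr <- xtr[, keep, drop = FALSE]
      xte <- xte[, keep, drop = FALSE]
      if (!is.null(layers)) lay <- layers[match(keep, colnames(x))]
    }
    sr <- run_search(xtr, ytr, grammar = grammar, control = control,
                     seed = derive_seed(seed, 100L + f), layers = lay)
    model <- sr$best$model
    test_ba <- balanced_accuracy(yte, predict(model, xte))
    per_fold[[f]] <- list(model = model,
                          train_ba = sr$best$fitness,
                          test_ba = test_ba,
                          expression = format(model, use_names = TRUE))
  }
  models <- lapply(per_fold, `[[`, "model")
  sel <- select_best_model(models,
                           test_ba = vapply(per_fold, `[[`, 0, "test_ba"))
  structure(list(per_fold = per_fold,
                 selected_model = sel,
                 consistency = variable_consistency(models),
                 folds = folds,
                 filter_logs = filter_logs,
                 control = control, seed = seed),
            class = "genn_cv")
}

#' Select the best model across folds
#'
#' "Identified the most" across cross-validations: fold-best models are
#' grouped by their variable set (weights and topology ignored) and the most
#' frequent group wins; its representative is the member with the highest
#' test accuracy. Frequency ties are broken by higher mean test accuracy,
#' then smaller model size.
#'
#' @param models list of fold-best \code{genn_network}s.
#' @param test_ba numeric vector of their test balanced accuracies (defaults
#'   to zeros, in which case selection is by frequency and size only).
#' @return The selected \code{genn_network}.
#' @export
select_best_model <- function(models, test_ba = rep(0, length(models))) {
  stopifnot(length(models) >= 1L, length(test_ba) == length(models))
  keys <- vapply(models, function(m) paste(sort(model_variables(m)),
                                           collapse = "\r"), "")
  groups <- split(seq_along(models), keys)
  freq <- vapply(groups, length, 0L)
  mean_ba <- vapply(groups, function(i) mean(test_ba[i]), 0)
  size <- vapply(groups, function(i) min(vapply(models[i], `[[`, 0L, "n_nodes")), 0)
  ord <- order(-freq, -mean_ba, size)
  winner <- groups[[ord[1L]]]
  rep_idx <- winner[which.max(test_ba[winner])]
  models[[rep_idx]]
}

#' Per-variable cross-validation consistency
#'
#' For every variable appearing in at least one fold-best model, the number of
#' folds whose best model contains it (e.g. 4/5). Variables in no model are
#' absent from the result.
#'
#' @param models list of fold-best \code{genn_network}s.
#' @return Named integer vector (descending counts).
#' @export
variable_consistency <- function(models) {
  vars <- unlist(lapply(models, function(m) unique(model_variables(m))))
  if (length(vars) == 0L) return(stats::setNames(integer(0), character(0)))
  tab <- sort(table(vars), decreasing = TRUE)
  stats::setNames(as.integer(tab), names(tab))
}

#' @export
print.genn_cv <- function(x, ...) {
  k <- length(x$per_fold)
  cat(k, "-fold cross-validated network search\n", sep = "")
  ba <- vapply(x$per_fold, `[[`, 0, "test_ba")
  cat("Test balanced accuracy per fold:",
      paste(sprintf("%.3f", ba), collapse = " "), "\n")
  cat("Mean test balanced accuracy:", sprintf("%.4f", mean(ba)), "\n")
  cat("Selected model:", format(x$selected_model, use_names = TRUE), "\n")
  invisible(x)
}

#' @export
summary.genn_cv <- function(object, ...) {
  ba <- vapply(object$per_fold, `[[`, 0, "test_ba")
  tr <- vapply(object$per_fold, `[[`, 0, "train_ba")
  out <- list(
    folds = data.frame(fold = seq_along(ba), train_ba = tr, test_ba = ba,
                       model = vapply(object$per_fold, `[[`, "", "expression")),
    mean_test_ba = mean(ba),
    consistency = object$consistency,
    selected = format(object$selected_model, use_names = TRUE))
  class(out) <- "summary.genn_cv"
  out
}

#' @export
print.summary.genn_cv <- function(x, ...) {
  print(x$folds, row.names = FALSE)
  cat("\nMean test balanced accuracy:", sprintf("%.4f", x$mean_test_ba), "\n")
  cat("Selected model:", x$selected, "\n")
  if (length(x$consistency) > 0L) {
    cat("Variable consistency (folds containing each variable):\n")
    print(x$consistency)
  }
  invisible(x)
}
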