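#' Fit a grammatical-evolution network classifier
#'
#' The main fitting function: evolves neural-network classifiers — weighted
#' activation-node trees over a subset of the input features — by grammatical
#' evolution under stratified k-fold cross-validation, optionally preceded by
#' the frequency-based filtering stage. The fitted object carries the
#' per-fold best models, their training/testing balanced accuracies, the
#' selected best model ("identified the most" across folds), and per-variable
#' cross-validation consistency.
#'
#' @param x samples x features numeric matrix (column names become model
#'   variable names), or an \code{\link{omics_dataset}} (in which case
#'   \code{y} defaults to its labels).
#' @param y binary outcome (0/1 or two-level factor); class 1 conventionally
#'   the short-term survival group.
#' @param grammar network grammar, default \code{\link{genn_grammar}()}.
#' @param control search hyper-parameters, a \code{\link{genn_control}}.
#' @param cv number of cross-validation folds.
#' @param filter \code{NULL}, a retention fraction in (0, 1), or a list
#'   \code{list(fraction=, control=)}; filtering is re-run inside each
#'   training fold.
#' @param seed integer seed; mandatory determinism — identical seeds give
#'   identical fits.
#' @param layers optional per-column layer names.
#' @return Object of class \code{genn} (extending \code{genn_cv}).
#' @examples
#' \donttest{
#' sim <- simulate_omics(sim_config(
#'   n_samples = 200, layers = c(expr = 20),
#'   effects = list(main_effect("expr", 1)), seed = 7))
#' fit <- genn(sim$datasets$expr,
#'             control = genn_control(demes = 2, pop_size = 100,
#'                                    generations = 10),
#'             seed = 7)
#' print(fit)
#' }
#' @export
genn <- function(x, y = NULL, grammar = genn_grammar(),
                 control = genn_control(), cv = 5L, filter = NULL,
                 seed = 1L, layers = NULL) {
  cl <- match.call()
  if (inherits(x, "omics_dataset")) {
    if (is.null(y)) y <- x$y
    if (is.null(layers)) layers <- rep(x$layer, ncol(x$x))
    x <- x$x
  }
  if (is.null(y)) stop("y is required when x is a plain matrix")
  fit <- run_cv(x, y, grammar = grammar, control = control, k = cv,
                seed = seed, filter = filter, layers = layers)
  fit$call <- cl
  fit$grammar <- grammar
  class(fit) <- c("genn", class(fit))
  fit
}

#' @export
print.genn <- function(x, ...) {
  cat("Grammatical-evolution network classifier\n")
  if (!is.null(x$call)) { cat("Call: "); print(x$call) }
  NextMethod()
}

#' Predict from a fitted genn classifier
#'
#' Applies the selected best model to new samples.
#'
#' @param object a fitted \code{\link{genn}}.
#' @param newdata samples x features matrix (or \code{omics_dataset})
#'   containing the selected model's variables.
#' @param type \code{"class"} or \code{"response"}.
#' @param ... unused.
#' @return Predicted classes or raw network outputs.
#' @export
predict.genn <- function(object, newdata, type = c("class", "response"), ...) {
  if (inherits(newdata, "omics_dataset")) newdata <- newdata$x
  predict(object$selected_model, newdata, type = match.arg(type))
}

#' Coefficients of the selected model
#'
#' The input weights of the selected network, one row per weighted input
#' (leaf inputs reference a feature; nested inputs a sub-node).
#'
#' @param object a fitted \code{\link{genn}}.
#' @param ... unused.
#' @return data.frame with columns \code{node}, \code{operator},
#'   \code{weight}, \code{input}.
#' @export
coef.genn <- function(object, ...) {
  m <- object$selected_model
  rows <- list()
  walk <- function(node, id) {
    if (node$type == "var") return(invisible())
    for (i in seq_along(node$inputs)) {
      inp <- node$inputs[[i]]
      lab <- if (inp$child$type == "var") {
        if (!is.null(m$var_names)) m$var_names[inp$child$index]
        else paste0("V", inp$child$index)
      } else paste0("node ", id, ".", i, " (", inp$child$op, ")")
      rows[[length(rows) + 1L]] <<- data.frame(
        node = id, operator = node$op, weight = inp$weight, input = lab,
        stringsAsFactors = FALSE)
      walk(inp$child, paste0(id, ".", i))
    }
  }
  walk(m$root, "1")
  do.call(rbind, rows)
}

#' Plot search / cross-validation summaries
#'
#' Bar plot of per-fold test balanced accuracies with the fold mean; a quick
#' visual of fit quality and fold stability.
#'
#' @param x a fitted \code{\link{genn}}.
#' @param ... passed to \code{barplot}.
#' @return Invisibly, the fold accuracies.
#' @export
plot.genn <- function(x, ...) {
  ba <- vapply(x$per_fold, `[[`, 0, "test_ba")
  bp <- graphics::barplot(ba, names.arg = paste("fold", seq_along(ba)),
                          ylim = c(0, 1),
                          ylab = "test balanced accuracy", ...)
  graphics::abline(h = mean(ba), lty = 2)
  graphics::abline(h = 0.5, col = "grey60")
  invisible(ba)
}

#' Write a plain-text model report
#'
#' Expression string of the selected model, its variables with layer of
#' origin and fold consistency, and per-fold balanced accuracies.
#'
#' @param fit a \code{\link{genn}} or \code{genn_cv} object.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_model_report <- function(fit, path) {
  con <- file(path, "w"); on.exit(close(con))
  m <- fit$selected_model
  writeLines(c("selected model:", paste0("  ", format(m, use_names = TRUE)), ""), con)
  vars <- model_variables(m)
  lay <- if (!is.null(m$var_layers)) m$var_layers[m$variables] else rep(NA, length(vars))
  writeLines("variable\tlayer\tconsistency", con)
  for (i in seq_along(vars))
    writeLines(paste(vars[i], lay[i],
                     if (vars[i] %in% names(fit$consistency))
                       fit$consistency[[vars[i]]] else 0L, sep = "\t"), con)
  writeLines(c("", "fold\ttrain_ba\ttest_ba\tmodel"), con)
  for (f in seq_along(fit$per_fold)) {
    pf <- fit$per_fold[[f]]
    writeLines(paste(f, sprintf("%.4f", pf$train_ba),
                     sprintf("%.4f", pf$test_ba), pf$expression, sep = "\t"), con)
  }
  invisible(path)
}
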