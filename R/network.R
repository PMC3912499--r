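#' @useDynLib gennet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Tree nodes are plain lists:
#   operator node: list(type = "node", op, inputs = list(list(weight, child), ...))
#   leaf:          list(type = "var",  index = <1-based variable index>)
# A genn_network wraps the root with its variable set and size; when a model is
# produced by a search against a concrete dataset, `var_names` / `var_layers`
# bind the indices to feature names and their omics layer of origin.

new_network <- function(root, var_names = NULL, var_layers = NULL) {
  vars <- sort(unique(collect_var_indices(root)))
  structure(list(root = root,
                 variables = vars,
                 n_nodes = count_nodes(root),
                 var_names = var_names,
                 var_layers = var_layers),
            class = "genn_network")
}

collect_var_indices <- function(node) {
  if (node$type == "var") return(node$index)
  unlist(lapply(node$inputs, function(inp) collect_var_indices(inp$child)))
}

count_nodes <- function(node) {
  if (node$type == "var") return(0L)
  1L + sum(vapply(node$inputs, function(inp) count_nodes(inp$child), 0L))
}

network_depth <- function(model) {
  depth1 <- function(node) {
    if (node$type == "var") return(0L)
    1L + max(vapply(node$inputs, function(inp) depth1(inp$child), 0L))
  }
  depth1(model$root)
}

#' Variable names used by a model
#'
#' @param model a \code{genn_network}.
#' @return Character vector: bound feature names when the model came from a
#'   search against a dataset, otherwise canonical \code{V<k>} names.
#' @export
model_variables <- function(model) {
  stopifnot(inherits(model, "genn_network"))
  if (!is.null(model$var_names)) model$var_names[model$variables]
  else paste0("V", model$variables)
}

#' Protected division
#'
#' Total division used by \code{PDIV} nodes: returns
#' \code{numerator/denominator} when \code{|denominator| >= 1e-10}, else the
#' protection value 1.0.
#'
#' @param numerator,denominator finite numerics (vectorised).
#' @return Numeric of the common length.
#' @export
protected_divide <- function(numerator, denominator) {
  out <- ifelse(abs(denominator) >= 1e-10, numerator / denominator, 1.0)
  ifelse(is.finite(out), out, 1.0)
}

#' Evaluate a network on feature data
#'
#' Recursively computes each activation node over weighted inputs
#' \eqn{a_i = w_i \times child_i}: \code{PADD} returns \eqn{\sum a_i},
#' \code{PSUB} returns \eqn{a_1 - a_2 (- a_3)}, \code{PMULT} returns
#' \eqn{\prod a_i}, and \code{PDIV} folds \code{\link{protected_divide}}
#' left-to-right. Any non-finite intermediate is replaced by the protection
#' value 1.0, so the output is always finite.
#'
#' @param model a \code{genn_network}.
#' @param features either a matrix/data.frame (samples x features; columns
#'   matched by the model's bound variable names, or by index \code{V<k>} for
#'   an unbound model) or a named numeric vector for a single sample.
#' @return Numeric vector of raw network outputs, one per sample.
#' @examples
#' m <- parse_network("PADD(1.0*V1,1.0*V2)")
#' evaluate_network(m, c(V1 = 0.5, V2 = 0.25))  # 0.75
#' @export
evaluate_network <- function(model, features) {
  stopifnot(inherits(model, "genn_network"))
  X <- feature_matrix_for(model, features)
  ev <- function(node) {
    if (node$type == "var") return(X[, match(node$index, model$variables)])
    vals <- lapply(node$inputs, function(inp) {
      a <- inp$weight * ev(inp$child)
      ifelse(is.finite(a), a, 1.0)
    })
    acc <- vals[[1L]]
    for (k in seq_along(vals)[-1L]) {
      acc <- switch(node$op,
                    PADD = acc + vals[[k]],
                    PSUB = acc - vals[[k]],
                    PMULT = acc * vals[[k]],
                    PDIV = protected_divide(acc, vals[[k]]),
                    stop("unknown operator ", node$op))
      acc <- ifelse(is.finite(acc), acc, 1.0)
    }
    acc
  }
  as.numeric(ev(model$root))
}

# Resolve the model's variables against user-supplied features; returns a
# samples x length(model$variables) matrix in model-variable order.
feature_matrix_for <- function(model, features) {
  wanted <- model_variables(model)
  if (is.numeric(features) && !is.matrix(features)) {
    features <- matrix(features, nrow = 1L,
                       dimnames = list(NULL, names(features)))
  }
  features <- as.matrix(features)
  if (!is.null(colnames(features))) {
    miss <- setdiff(wanted, colnames(features))
    if (length(miss) > 0L)
      stop("variable(s) missing from features: ", paste(miss, collapse = ", "))
    X <- features[, wanted, drop = FALSE]
  } else {
    if (ncol(features) < max(model$variables))
      stop("variable V", max(model$variables), " missing from features")
    X <- features[, model$variables, drop = FALSE]
  }
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("non-finite feature values supplied")
  X
}

#' Predict binary class from a network
#'
#' The raw network output is thresholded at zero: output \eqn{\ge} 0 gives
#' class 1, otherwise class 0.
#'
#' @param object a \code{genn_network}.
#' @param newdata features as in \code{\link{evaluate_network}}.
#' @param type \code{"class"} (default) or \code{"response"} (raw output).
#' @param ... unused.
#' @return Integer vector of classes, or numeric outputs for
#'   \code{type = "response"}.
#' @export
predict.genn_network <- function(object, newdata, type = c("class", "response"),
                                 ...) {
  type <- match.arg(type)
  out <- evaluate_network(object, newdata)
  if (type == "response") out else as.integer(out >= 0)
}

fmt_weight <- function(w) {
  s <- sprintf("%.10g", w)
  if (!grepl("[.e]", s)) s <- paste0(s, ".0")
  s
}

#' Canonical expression string of a network
#'
#' Form \code{OP(w*arg,w*arg[,w*arg])} with weights printed with at least one
#' decimal; nested nodes appear with their explicit weight. Variables print as
#' \code{V<k>} so that \code{\link{parse_network}} round-trips the tree; set
#' \code{use_names = TRUE} to show bound feature names instead.
#'
#' @param x a \code{genn_network}.
#' @param use_names print bound feature names for variables.
#' @param ... unused.
#' @return A character scalar.
#' @export
format.genn_network <- function(x, use_names = FALSE, ...) {
  leaf_lab <- function(idx) {
    if (use_names && !is.null(x$var_names)) x$var_names[idx]
    else paste0("V", idx)
  }
  fmt <- function(node) {
    if (node$type == "var") return(leaf_lab(node$index))
    args <- vapply(node$inputs, function(inp)
      paste0(fmt_weight(inp$weight), "*", fmt(inp$child)), "")
    paste0(node$op, "(", paste(args, collapse = ","), ")")
  }
  fmt(x$root)
}

#' @export
print.genn_network <- function(x, ...) {
  cat("Evolved network (", x$n_nodes, " nodes, ",
      length(x$variables), " variables)\n", sep = "")
  cat("  ", format(x), "\n", sep = "")
  if (!is.null(x$var_names)) {
    lay <- if (!is.null(x$var_layers)) paste0(" [", x$var_layers[x$variables], "]") else ""
    cat("  variables: ",
        paste0(paste0("V", x$variables), " = ", x$var_names[x$variables], lay,
               collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Parse a canonical expression string into a network
#'
#' Inverse of \code{\link{format.genn_network}}: accepts
#' \code{OP(w*arg,...)} with operators \code{PADD}, \code{PSUB}, \code{PMULT},
#' \code{PDIV}, decimal weights, and \code{V<k>} variables. Malformed input
#' raises an error reporting the character position.
#'
#' @param text expression string.
#' @return A \code{genn_network}.
#' @export
parse_network <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("[[:space:]]", "", text)
  pos <- 1L
  n <- nchar(s)
  peek <- function(k = 1L) if (pos + k - 1L <= n) substr(s, pos, pos + k - 1L) else ""
  fail <- function(msg) stop("parse error at position ", pos, ": ", msg, call. = FALSE)
  expect <- function(ch) {
    if (peek() != ch) fail(paste0("expected '", ch, "'"))
    pos <<- pos + 1L
  }
  parse_node <- function() {
    op <- NULL
    for (cand in c("PADD", "PSUB", "PMULT", "PDIV")) {
      if (peek(nchar(cand)) == cand) { op <- cand; break }
    }
    if (is.null(op)) fail("expected operator (PADD/PSUB/PMULT/PDIV)")
    pos <<- pos + nchar(op)
    expect("(")
    inputs <- list(parse_winput())
    while (peek() == ",") { pos <<- pos + 1L; inputs <- c(inputs, list(parse_winput())) }
    expect(")")
    if (length(inputs) < 2L || length(inputs) > 3L)
      fail("nodes take 2 or 3 weighted inputs")
    list(type = "node", op = op, inputs = inputs)
  }
  parse_winput <- function() {
    start <- pos
    while (grepl("[-+0-9.eE]", peek()) && nzchar(peek())) pos <<- pos + 1L
    if (pos == start) fail("expected a numeric weight")
    w <- suppressWarnings(as.numeric(substr(s, start, pos - 1L)))
    if (is.na(w)) { pos <<- start; fail("malformed weight") }
    expect("*")
    child <- if (peek() == "V") parse_var() else parse_node()
    list(weight = w, child = child)
  }
  parse_var <- function() {
    expect("V")
    start <- pos
    while (grepl("[0-9]", peek()) && nzchar(peek())) pos <<- pos + 1L
    if (pos == start) fail("expected variable index after 'V'")
    list(type = "var", index = as.integer(substr(s, start, pos - 1L)))
  }
  root <- parse_node()
  if (pos <= n) fail("trailing input")
  new_network(root)
}

# Build a genn_network from mapper tokens (used by the search), binding
# variable indices to dataset feature names.
network_from_tokens <- function(tokens, terminals, var_names = NULL,
                                var_layers = NULL) {
  m <- parse_network(tokens_to_string(tokens, terminals))
  m$var_names <- var_names
  m$var_layers <- var_layers
  m
}
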