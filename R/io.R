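#' Construct an omics dataset
#'
#' A labelled samples x features matrix for one genomic layer (e.g. copy
#' number cytobands, CpG methylation, miRNA, gene expression).
#'
#' @param x numeric matrix (samples x features) with unique row (sample) and
#'   column (feature) names.
#' @param y classes (0/1), one per sample; class 1 conventionally encodes the
#'   short-term survival group.
#' @param layer layer name.
#' @return Object of class \code{omics_dataset}: list with \code{x},
#'   \code{y} (named), \code{layer}.
#' @export
omics_dataset <- function(x, y, layer = "data") {
  x <- as_feature_matrix(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("S", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("F", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(x))) stop("duplicate feature names in layer ", layer)
  y <- as_binary(y)
  stopifnot(length(y) == nrow(x))
  structure(list(x = x, y = stats::setNames(y, rownames(x)), layer = layer),
            class = "omics_dataset")
}

#' @export
print.omics_dataset <- function(x, ...) {
  cat("Omics layer '", x$layer, "': ", nrow(x$x), " samples x ", ncol(x$x),
      " features (", sum(x$y == 1), " class-1 / ", sum(x$y == 0),
      " class-0)\n", sep = "")
  invisible(x)
}

#' Read an omics matrix from tab-delimited text
#'
#' Expected dialect: header row of feature names; first column the sample
#' identifier; one column (default \code{"class"}) holding the binary label
#' as 0/1 or short/long (short-term survival = class 1); remaining columns
#' numeric features with \code{NA} as the missing token. Missing cells are
#' imputed by their feature's median. Labels can instead be supplied
#' separately as a named vector via \code{labels}.
#'
#' @param path file path.
#' @param layer layer name for the resulting dataset.
#' @param label_col name of the label column inside the file (ignored when
#'   \code{labels} is given).
#' @param labels optional named 0/1 vector of labels keyed by sample id.
#' @return An \code{\link{omics_dataset}}.
#' @export
read_omics <- function(path, layer = "data", label_col = "class",
                       labels = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected a sample-id column plus feature columns")
  ids <- as.character(df[[1L]])
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicated sample id(s): ", paste(unique(dup), collapse = ", "))
  df <- df[, -1L, drop = FALSE]
  if (is.null(labels)) {
    if (!label_col %in% names(df))
      stop("label column '", label_col, "' not found (and no labels supplied)")
    y <- parse_labels(df[[label_col]])
    df <- df[, setdiff(names(df), label_col), drop = FALSE]
  } else {
    miss <- setdiff(ids, names(labels))
    if (length(miss) > 0L)
      stop("no label for sample(s): ", paste(miss, collapse = ", "))
    y <- as_binary(labels[ids])
  }
  x <- matrix(NA_real_, nrow = length(ids), ncol = ncol(df),
              dimnames = list(ids, names(df)))
  for (j in seq_len(ncol(df))) {
    col <- df[[j]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col) & col != "NA")
    if (length(bad) > 0L)
      stop("non-numeric value '", col[bad[1L]], "' at row ", bad[1L],
           ", column '", names(df)[j], "'")
    if (anyNA(num)) num[is.na(num)] <- stats::median(num, na.rm = TRUE)
    x[, j] <- num
  }
  omics_dataset(x, y, layer = layer)
}

parse_labels <- function(v) {
  if (is.character(v)) {
    v <- trimws(tolower(v))
    if (all(v %in% c("short", "long"))) return(as.integer(v == "short"))
    num <- suppressWarnings(as.numeric(v))
    if (anyNA(num)) stop("labels must be 0/1 or short/long; got '",
                         v[which(is.na(num))[1L]], "'")
    v <- num
  }
  if (!all(v %in% c(0, 1))) stop("labels must be 0/1 or short/long")
  as.integer(v)
}

#' Write an omics dataset as tab-delimited text
#'
#' Inverse of \code{\link{read_omics}}: sample-id column, \code{class}
#' column, then features.
#'
#' @param dataset an \code{\link{omics_dataset}}.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_omics <- function(dataset, path) {
  stopifnot(inherits(dataset, "omics_dataset"))
  df <- data.frame(sample = rownames(dataset$x),
                   class = as.integer(dataset$y),
                   dataset$x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict layers to their common samples
#'
#' Restricts every dataset to the intersection of sample ids, in the order of
#' the first dataset; labels must agree across layers. Idempotent.
#'
#' @param datasets list of \code{\link{omics_dataset}}s.
#' @return List of aligned datasets.
#' @export
align_samples <- function(datasets) {
  stopifnot(length(datasets) >= 1L,
            all(vapply(datasets, inherits, TRUE, "omics_dataset")))
  common <- Reduce(intersect, lapply(datasets, function(d) rownames(d$x)))
  if (length(common) == 0L) stop("no samples shared by all layers")
  common <- rownames(datasets[[1L]]$x)[rownames(datasets[[1L]]$x) %in% common]
  ref <- datasets[[1L]]$y[common]
  lapply(datasets, function(d) {
    y <- d$y[common]
    bad <- which(y != ref)
    if (length(bad) > 0L)
      stop("conflicting labels between layers '", datasets[[1L]]$layer,
           "' and '", d$layer, "' for sample(s): ",
           paste(common[bad], collapse = ", "))
    omics_dataset(d$x[common, , drop = FALSE], y, layer = d$layer)
  })
}

standardize_stats <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  list(mean = mu, sd = sdv)
}

apply_standardize <- function(x, st) {
  z <- sweep(x, 2L, st$mean, "-")
  s <- ifelse(st$sd > 0 & is.finite(st$sd), st$sd, Inf)  # constant -> zeros
  sweep(z, 2L, s, "/")
}

#' Z-score the features of a dataset
#'
#' Each feature is centred and scaled to unit sample standard deviation;
#' zero-variance features map to all zeros. When \code{train_idx} is given,
#' the statistics come from those samples only (fold-aware standardization,
#' avoiding test-set leakage) but are applied to all samples.
#'
#' @param dataset an \code{\link{omics_dataset}} or a plain matrix.
#' @param train_idx optional logical/integer index of training samples.
#' @return Object of the same kind, standardized.
#' @export
standardize_features <- function(dataset, train_idx = NULL) {
  x <- if (inherits(dataset, "omics_dataset")) dataset$x else as_feature_matrix(dataset)
  st <- standardize_stats(if (is.null(train_idx)) x else x[train_idx, , drop = FALSE])
  z <- apply_standardize(x, st)
  if (inherits(dataset, "omics_dataset"))
    omics_dataset(z, dataset$y, layer = dataset$layer)
  else z
}
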