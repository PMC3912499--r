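#' Balanced classification accuracy
#'
#' \eqn{(sensitivity + specificity)/2}; the fitness function of the search.
#' Robust to class imbalance: a constant predictor scores 0.5 on any dataset
#' containing both classes.
#'
#' @param truth observed classes (0/1, logical, or a two-level factor).
#' @param predicted predicted classes, same encoding.
#' @return Balanced accuracy in \code{[0, 1]}.
#' @examples
#' balanced_accuracy(c(1, 1, 1, 1, 0, 0, 0, 0), c(1, 1, 1, 0, 0, 0, 1, 1))
#' @export
balanced_accuracy <- function(truth, predicted) {
  truth <- as_binary(truth)
  predicted <- as_binary(predicted)
  stopifnot(length(truth) == length(predicted))
  balanced_accuracy_counts(tp = sum(truth == 1 & predicted == 1),
                           fp = sum(truth == 0 & predicted == 1),
                           tn = sum(truth == 0 & predicted == 0),
                           fn = sum(truth == 1 & predicted == 0))
}

#' @rdname balanced_accuracy
#' @param tp,fp,tn,fn confusion counts (non-negative integers).
#' @export
balanced_accuracy_counts <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  if (tp + fn < 1 || tn + fp < 1)
    stop("balanced accuracy requires both classes present (tp+fn >= 1 and tn+fp >= 1)")
  ((tp / (tp + fn)) + (tn / (tn + fp))) / 2
}

as_binary <- function(x) {
  if (is.factor(x)) x <- as.integer(x) - 1L
  if (is.logical(x)) x <- as.integer(x)
  stopifnot(all(x %in% c(0L, 1L)))
  as.integer(x)
}

#' Exact Wilcoxon signed-rank test for paired accuracies
#'
#' Compares two equal-length sequences of per-fold accuracies by the signed
#' ranks of their differences. Zero differences are dropped before ranking
#' (Wilcoxon's original treatment); tied absolute differences receive average
#' ranks. The null distribution of \eqn{W} (sum of positive ranks) is obtained
#' by full enumeration of all \eqn{2^m} sign assignments of the \eqn{m}
#' nonzero differences, so the p-value is exact even under ties — essential
#' here, where \eqn{m \le 5} and any large-sample approximation is
#' meaningless. The two-sided p doubles the smaller one-sided tail, capped
#' at 1.
#'
#' @param a,b paired accuracy sequences (equal length).
#' @param sides \code{"two"} (default) or \code{"one"}; the one-sided
#'   alternative is \code{a > b}.
#' @return List with \code{statistic} (W), \code{p_value}, and \code{n_used}
#'   (nonzero differences).
#' @examples
#' wilcoxon_exact(c(.72, .70, .74, .69, .71), c(.61, .66, .64, .65, .60))$p_value  # 0.0625
#' @export
wilcoxon_exact <- function(a, b, sides = c("two", "one")) {
  sides <- match.arg(sides)
  stopifnot(length(a) == length(b), length(a) >= 1)
  d <- as.numeric(a) - as.numeric(b)
  d <- d[d != 0]
  m <- length(d)
  if (m == 0L)
    return(list(statistic = 0, p_value = 1.0, n_used = 0L))
  if (m > 20L)
    stop("exact enumeration supported for at most 20 nonzero differences")
  r <- rank(abs(d))                       # average ranks under ties
  W <- sum(r[d > 0])
  # all 2^m sign assignments: row s of the 0/1 matrix selects positive ranks
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  Wnull <- as.numeric(signs %*% r)
  eps <- 1e-9
  p_ge <- mean(Wnull >= W - eps)          # P(W* >= W), tail for a > b
  p <- if (sides == "one") {
    p_ge
  } else {
    p_le <- mean(Wnull <= W + eps)
    min(1, 2 * min(p_ge, p_le))
  }
  list(statistic = W, p_value = p, n_used = m)
}
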