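#' Intermediate models of a search log
#'
#' The filtering stage defines "intermediate models" as the best model of
#' every (generation, deme) pair of a search — a short, wide search therefore
#' yields \code{generations x demes} models per run. Accepts a single
#' \code{genn_search} or a list of them (e.g. one per cross-validation fold);
#' logs only ever record valid individuals.
#'
#' @param searches a \code{genn_search} or list of \code{genn_search} objects.
#' @return List of \code{genn_network} models.
#' @export
collect_intermediate_models <- function(searches) {
  if (inherits(searches, "genn_search")) searches <- list(searches)
  out <- list()
  for (s in searches) {
    stopifnot(inherits(s, "genn_search"))
    for (deme_log in s$log_models) {
      for (tokens in deme_log) {
        out[[length(out) + 1L]] <-
          network_from_tokens(tokens, s$terminals,
                              var_names = s$var_names,
                              var_layers = s$var_layers)
      }
    }
  }
  out
}

#' Variable frequency table from intermediate models
#'
#' frequency(v) = fraction of models whose variable set contains v (multiple
#' occurrences within one model count once). Variables never appearing get
#' frequency 0 and the worst ranks. Rank ties are resolved by stable sort on
#' descending frequency, then input order of the variables.
#'
#' @param models list of \code{genn_network}s (or, equivalently, of the
#'   character variable sets of the models).
#' @param all_variables character vector of every variable of the layer, in
#'   input-file order.
#' @param layers optional per-variable layer names (same length).
#' @return data.frame of class \code{genn_freq} with columns
#'   \code{variable}, \code{layer}, \code{frequency}, \code{rank}, sorted by
#'   rank; attribute \code{n_models}.
#' @export
variable_frequency <- function(models, all_variables, layers = NULL) {
  stopifnot(length(models) >= 1L)
  counts <- stats::setNames(numeric(length(all_variables)), all_variables)
  for (m in models) {
    v <- unique(if (inherits(m, "genn_network")) model_variables(m) else m)
    v <- v[v %in% all_variables]
    counts[v] <- counts[v] + 1
  }
  freq <- counts / length(models)
  ord <- order(-freq, seq_along(freq))
  tab <- data.frame(variable = all_variables[ord],
                    layer = if (is.null(layers)) NA_character_ else layers[ord],
                    frequency = as.numeric(freq[ord]),
                    rank = seq_along(freq),
                    stringsAsFactors = FALSE)
  attr(tab, "n_models") <- length(models)
  class(tab) <- c("genn_freq", "data.frame")
  tab
}

#' Retain the top fraction of variables
#'
#' Keeps the \code{ceiling(fraction * p)} best-ranked variables of a frequency
#' table with \code{p} rows, so any positive fraction retains at least one
#' variable, and retained sets are nested across increasing fractions.
#'
#' @param table a \code{genn_freq} table.
#' @param fraction retention fraction in (0, 1]; 1 disables the filter.
#' @return Character vector of retained variable names (rank order).
#' @export
apply_threshold <- function(table, fraction) {
  stopifnot(inherits(table, "data.frame"), fraction > 0, fraction <= 1)
  p <- nrow(table)
  keep <- ceiling(fraction * p)
  table$variable[order(table$rank)][seq_len(keep)]
}

#' Frequency-based filtering of one dataset
#'
#' Runs a short, wide search on \code{(x, y)} and tabulates how often each
#' variable appears among the intermediate models. The default configuration
#' (10 demes x 500 individuals, 20 generations) mirrors the published
#' filtering stage at desk scale.
#'
#' @param x samples x features matrix with column names.
#' @param y classes (0/1).
#' @param grammar a \code{genn_grammar}.
#' @param control a \code{\link{genn_control}} for the filtering search.
#' @param seed integer seed.
#' @param layers optional per-column layer names.
#' @return A \code{genn_freq} table (see \code{\link{variable_frequency}}).
#' @export
genn_filter <- function(x, y, grammar = genn_grammar(),
                        control = genn_control(demes = 10L, pop_size = 500L,
                                                generations = 20L,
                                                migrations = 1L),
                        seed = 1L, layers = NULL) {
  x <- as_feature_matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  s <- run_search(x, y, grammar = grammar, control = control, seed = seed,
                  layers = layers)
  variable_frequency(log_variable_sets(s),
                     all_variables = colnames(x), layers = layers)
}

# Variable sets of every logged (generation, deme) best, straight from the
# token vectors (negative tokens are variable indices) — avoids parsing full
# expression trees when only the variable sets are needed.
log_variable_sets <- function(search) {
  nm <- search$var_names
  out <- list()
  for (deme_log in search$log_models) {
    for (tokens in deme_log) {
      idx <- sort(unique(-tokens[tokens < 0L]))
      out[[length(out) + 1L]] <- if (is.null(nm)) paste0("V", idx) else nm[idx]
    }
  }
  out
}

#' Choose a retention fraction by cross-validated accuracy
#'
#' For each candidate fraction, runs the filtered cross-validation protocol
#' (\code{\link{run_cv}} with per-fold filtering) and returns the fraction
#' with the highest mean test balanced accuracy — the comparison used to pick
#' the per-layer thresholds among top 10/30/50\%.
#'
#' @param x,y data as in \code{\link{run_cv}}.
#' @param candidate_fractions numeric vector of fractions in (0, 1].
#' @param grammar a \code{genn_grammar}.
#' @param eval_control \code{genn_control} for the modelling searches.
#' @param filter_control \code{genn_control} for the filtering searches.
#' @param k folds.
#' @param seed integer seed (shared fold assignment across candidates).
#' @return List with \code{best_fraction} and \code{results} (data.frame:
#'   fraction, mean test balanced accuracy).
#' @export
select_filter_threshold <- function(x, y, candidate_fractions = c(0.1, 0.3, 0.5),
                                    grammar = genn_grammar(),
                                    eval_control = genn_control(),
                                    filter_control = genn_control(
                                      demes = 10L, pop_size = 500L,
                                      generations = 20L, migrations = 1L),
                                    k = 5L, seed = 1L) {
  stopifnot(length(candidate_fractions) >= 1L)
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  folds <- split_folds(ids, y, k = k, seed = seed)
  mean_ba <- vapply(candidate_fractions, function(fr) {
    filt <- if (fr >= 1) NULL else list(fraction = fr, control = filter_control)
    cvr <- run_cv(x, y, grammar = grammar, control = eval_control,
                  seed = seed, folds = folds, filter = filt)
    mean(vapply(cvr$per_fold, `[[`, 0, "test_ba"))
  }, 0)
  list(best_fraction = candidate_fractions[which.max(mean_ba)],
       results = data.frame(fraction = candidate_fractions,
                            mean_test_ba = mean_ba))
}
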