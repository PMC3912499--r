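#' Planted effects for the synthetic generator
#'
#' \code{main_effect} plants a single-variable signal: a sample is "at risk"
#' when its value of the planted feature exceeds 0. \code{xor_effect} plants a
#' two-variable non-linear interaction (within one layer or across two): the
#' risk state is the exclusive-or of the two features' threshold states, so
#' each variable alone carries no marginal association with the outcome —
#' the epistasis/synthetic-lethality pattern that motivates non-linear
#' searches.
#'
#' @param layer,layer1,layer2 layer names.
#' @param feature,feature1,feature2 1-based feature indices within the layer.
#' @param penetrance_high probability of class 1 given risk state 1.
#' @param penetrance_low probability of class 1 given risk state 0.
#' @return A list of class \code{genn_effect}.
#' @export
main_effect <- function(layer, feature, penetrance_high = 0.9,
                        penetrance_low = 0.1) {
  new_effect("main", list(c(layer = layer, feature = feature)),
             penetrance_high, penetrance_low)
}

#' @rdname main_effect
#' @export
xor_effect <- function(layer1, feature1, layer2, feature2,
                       penetrance_high = 0.9, penetrance_low = 0.1) {
  if (layer1 == layer2 && feature1 == feature2)
    stop("xor_effect requires two distinct variables")
  new_effect("xor_pair", list(c(layer = layer1, feature = feature1),
                              c(layer = layer2, feature = feature2)),
             penetrance_high, penetrance_low)
}

new_effect <- function(kind, variables, penetrance_high, penetrance_low) {
  # equality allowed so a no-signal effect (p_h == p_l) is expressible
  stopifnot(penetrance_low >= 0, penetrance_high <= 1,
            penetrance_low <= penetrance_high)
  structure(list(kind = kind, variables = variables,
                 penetrance_high = penetrance_high,
                 penetrance_low = penetrance_low),
            class = "genn_effect")
}

#' Simulation configuration
#'
#' Defaults mimic the shape of a multi-omics study at desk scale: 4 layers of
#' 100 continuous features and 500 samples, penetrances 0.9/0.1.
#'
#' @param n_samples number of samples (>= 20).
#' @param layers named integer vector: features per layer.
#' @param effects list of \code{\link{main_effect}} / \code{\link{xor_effect}}.
#' @param seed integer seed.
#' @return A list of class \code{genn_sim_config}.
#' @export
sim_config <- function(n_samples = 500L,
                       layers = c(cna = 100L, methylation = 100L,
                                  mirna = 100L, expression = 100L),
                       effects = list(), seed = 1L) {
  stopifnot(n_samples >= 20L, length(layers) >= 1L, !is.null(names(layers)),
            all(layers >= 1L))
  if (inherits(effects, "genn_effect")) effects <- list(effects)
  for (e in effects) {
    stopifnot(inherits(e, "genn_effect"))
    for (v in e$variables) {
      lay <- v[["layer"]]; idx <- as.integer(v[["feature"]])
      if (!lay %in% names(layers))
        stop("effect references unknown layer '", lay, "'")
      if (idx < 1L || idx > layers[[lay]])
        stop("effect feature index ", idx, " outside layer '", lay, "'")
    }
  }
  structure(list(n_samples = as.integer(n_samples), layers = layers,
                 effects = effects, seed = as.integer(seed)),
            class = "genn_sim_config")
}

#' Generate synthetic multi-layer omics data with planted effects
#'
#' All features are independent standard normals. For each sample a latent
#' risk state is computed from the planted effects (main: value > 0;
#' xor_pair: exclusive-or of the two threshold states). The class is drawn
#' Bernoulli(penetrance_high) when any effect is active — using the largest
#' penetrance_high among active effects — else Bernoulli(penetrance_low)
#' (largest among effects); with no effects the class is Bernoulli(0.5).
#'
#' @param config a \code{\link{sim_config}}.
#' @return List with \code{datasets} (named list of
#'   \code{\link{omics_dataset}}s sharing one sample set) and \code{truth}
#'   (the planted effects).
#' @export
simulate_omics <- function(config) {
  stopifnot(inherits(config, "genn_sim_config"))
  with_seed(config$seed, {
    n <- config$n_samples
    ids <- sprintf("S%04d", seq_len(n))
    mats <- lapply(names(config$layers), function(lay) {
      p <- config$layers[[lay]]
      m <- matrix(stats::rnorm(n * p), nrow = n,
                  dimnames = list(ids, sprintf("%s_f%03d", lay, seq_len(p))))
      m
    })
    names(mats) <- names(config$layers)
    if (length(config$effects) == 0L) {
      y <- stats::rbinom(n, 1L, 0.5)
    } else {
      risk <- matrix(FALSE, nrow = n, ncol = length(config$effects))
      for (k in seq_along(config$effects)) {
        e <- config$effects[[k]]
        states <- vapply(e$variables, function(v)
          mats[[v[["layer"]]]][, as.integer(v[["feature"]])] > 0,
          logical(n))
        risk[, k] <- if (e$kind == "main") states[, 1L] else xor(states[, 1L], states[, 2L])
      }
      ph <- vapply(config$effects, `[[`, 0, "penetrance_high")
      pl <- vapply(config$effects, `[[`, 0, "penetrance_low")
      p1 <- ifelse(rowSums(risk) > 0,
                   apply(risk, 1L, function(r) if (any(r)) max(ph[r]) else NA_real_),
                   max(pl))
      y <- stats::rbinom(n, 1L, p1)
    }
    datasets <- lapply(names(mats), function(lay)
      omics_dataset(mats[[lay]], y, layer = lay))
    names(datasets) <- names(mats)
    list(datasets = datasets, truth = config$effects)
  })
}

#' Oracle balanced accuracy of a single planted effect
#'
#' The performance ceiling of a simulation: the balanced accuracy of the
#' oracle predicting class 1 exactly on risk state 1. Since the risk state has
#' probability 1/2 under the generator, sensitivity is
#' \eqn{p_h/(p_h + p_l)} and specificity \eqn{(1-p_l)/((1-p_h) + (1-p_l))};
#' for penetrances (0.9, 0.1) both equal 0.9.
#'
#' @param config a \code{\link{sim_config}} with exactly one effect.
#' @return Expected balanced accuracy of the oracle.
#' @export
bayes_accuracy <- function(config) {
  stopifnot(inherits(config, "genn_sim_config"))
  if (length(config$effects) != 1L)
    stop("bayes_accuracy is defined for single-effect configurations only")
  e <- config$effects[[1L]]
  ph <- e$penetrance_high; pl <- e$penetrance_low
  sens <- ph / (ph + pl)
  spec <- (1 - pl) / ((1 - ph) + (1 - pl))
  (sens + spec) / 2
}
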