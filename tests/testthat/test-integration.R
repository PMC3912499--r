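mk_layers <- function(n = 30, seed = 1) {
  set.seed(seed)
  ids <- paste0("s", 1:n)
  y <- stats::setNames(rep_len(c(0L, 1L), n), ids)
  mk <- function(layer, p) {
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(ids, paste0(layer, "_f", 1:p)))
    omics_dataset(x, y, layer = layer)
  }
  list(mirna = mk("mirna", 6), methyl = mk("methyl", 8),
       expr = mk("expr", 5), cna = mk("cna", 4))
}

test_that("pooling takes the union of best-model variables, layer-qualified", {
  layers <- mk_layers()
  best <- list(
    mirna = structure(parse_network("PADD(1.0*V1,1.0*V2)"),
                      var_names = NULL),
    methyl = parse_network("PSUB(1.0*V1,1.0*V3)"),
    expr = parse_network("PMULT(1.0*V2,1.0*V4)"),
    cna = parse_network("PADD(1.0*V1,1.0*V1)"))
  # bind variable names per layer
  for (lay in names(best)) best[[lay]]$var_names <- colnames(layers[[lay]]$x)
  pooled <- pool_best_variables(best, layers)
  expect_identical(ncol(pooled$x), 2L + 2L + 2L + 1L)
  expect_true(all(grepl("^(mirna|methyl|expr|cna):", colnames(pooled$x))))
  # feature values are copied bitwise from their source layers
  expect_identical(unname(pooled$x[, "mirna:mirna_f1"]),
                   unname(layers$mirna$x[, "mirna_f1"]))
  expect_identical(unname(pooled$x[, "cna:cna_f1"]),
                   unname(layers$cna$x[, "cna_f1"]))
  # an absent best model contributes nothing
  pooled2 <- pool_best_variables(best[c("mirna", "methyl")], layers)
  expect_identical(ncol(pooled2$x), 4L)
  # same-named features in different layers stay distinct
  expect_identical(anyDuplicated(colnames(pooled$x)), 0L)
})

test_that("a best-model variable missing from its layer is an error", {
  layers <- mk_layers()
  ghost <- parse_network("PADD(1.0*V1,1.0*V2)")
  ghost$var_names <- c("nope_1", "nope_2")
  expect_error(pool_best_variables(list(mirna = ghost), layers), "missing")
})

test_that("integration produces one paired comparison per layer", {
  layers <- mk_layers(n = 60, seed = 2)
  small <- genn_control(demes = 1, pop_size = 30, generations = 3)
  ig <- genn_integrate(layers, control = small, layer_control = small,
                       k = 3, seed = 4)
  expect_identical(nrow(ig$comparisons), 4L)
  expect_setequal(ig$comparisons$layer, names(layers))
  expect_true(all(ig$comparisons$p_value > 0 & ig$comparisons$p_value <= 1))
  expect_length(ig$fold_accuracies, 3L)
  # the final model's variables come from the pooled set
  expect_true(all(model_variables(ig$final_model) %in% colnames(ig$pooled$x)))
})

test_that("pooling modes widen the search space as documented", {
  layers <- mk_layers(n = 60, seed = 3)
  small <- genn_control(demes = 1, pop_size = 30, generations = 3)
  ig_best <- genn_integrate(layers, control = small, layer_control = small,
                            k = 3, seed = 5, pool = "best")
  ig_folds <- genn_integrate(layers, control = small, layer_control = small,
                             k = 3, seed = 5, pool = "folds")
  ig_layers <- genn_integrate(layers, control = small, layer_control = small,
                              k = 3, seed = 5, pool = "layers")
  expect_lte(ncol(ig_best$pooled$x), ncol(ig_folds$pooled$x))
  expect_identical(ncol(ig_layers$pooled$x), 6L + 8L + 5L + 4L)
})
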