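test_that("generation is seed-reproducible and structurally valid", {
  cfg <- sim_config(n_samples = 50, layers = c(a = 10, b = 5),
                    effects = list(main_effect("a", 2)), seed = 3)
  g1 <- simulate_omics(cfg)
  g2 <- simulate_omics(cfg)
  expect_identical(g1$datasets$a$x, g2$datasets$a$x)
  expect_identical(g1$datasets$b$y, g2$datasets$b$y)
  expect_identical(dim(g1$datasets$a$x), c(50L, 10L))
  expect_identical(dim(g1$datasets$b$x), c(50L, 5L))
  # shared sample set and labels across layers
  expect_identical(rownames(g1$datasets$a$x), rownames(g1$datasets$b$x))
  expect_identical(g1$datasets$a$y, g1$datasets$b$y)
  # generated layers feed the rest of the pipeline
  expect_s3_class(g1$datasets$a, "omics_dataset")
})

test_that("effect references outside a layer are rejected", {
  expect_error(sim_config(layers = c(a = 10),
                          effects = list(main_effect("a", 11))), "outside")
  expect_error(sim_config(layers = c(a = 10),
                          effects = list(main_effect("z", 1))), "unknown layer")
  expect_error(xor_effect("a", 1, "a", 1), "distinct")
})

test_that("no-effect data has a balanced class fraction", {
  g <- simulate_omics(sim_config(n_samples = 10000, layers = c(a = 2),
                                 seed = 5))
  expect_lt(abs(mean(g$datasets$a$y) - 0.5), 0.02)
})

test_that("penetrance is honoured conditional on the XOR risk state", {
  cfg <- sim_config(n_samples = 10000, layers = c(a = 3, b = 3),
                    effects = list(xor_effect("a", 1, "b", 2, 0.9, 0.1)),
                    seed = 8)
  g <- simulate_omics(cfg)
  state <- xor(g$datasets$a$x[, 1] > 0, g$datasets$b$x[, 2] > 0)
  y <- g$datasets$a$y
  expect_lt(abs(mean(y[state]) - 0.9), 0.02)
  expect_lt(abs(mean(y[!state]) - 0.1), 0.02)
})

test_that("XOR components have null marginal association", {
  cfg <- sim_config(n_samples = 10000, layers = c(a = 3, b = 3),
                    effects = list(xor_effect("a", 1, "b", 2, 0.9, 0.1)),
                    seed = 21)
  g <- simulate_omics(cfg)
  y <- g$datasets$a$y
  for (v in list(g$datasets$a$x[, 1], g$datasets$b$x[, 2])) {
    expect_lte(abs(stats::cor(as.integer(v > 0), y)), 0.05)
  }
})

test_that("the oracle accuracy ceiling follows the penetrances", {
  mk <- function(ph, pl) sim_config(n_samples = 100, layers = c(a = 3),
                                    effects = list(main_effect("a", 1, ph, pl)))
  expect_equal(bayes_accuracy(mk(1.0, 0.0)), 1.0)
  expect_equal(bayes_accuracy(mk(0.5, 0.5)), 0.5)
  expect_equal(bayes_accuracy(mk(0.9, 0.1)), 0.9)
  expect_error(bayes_accuracy(sim_config(n_samples = 100, layers = c(a = 3))),
               "single-effect")
})

test_that("the empirical oracle matches bayes_accuracy by simulation", {
  cfg <- sim_config(n_samples = 10000, layers = c(a = 2),
                    effects = list(main_effect("a", 1, 0.9, 0.1)), seed = 14)
  g <- simulate_omics(cfg)
  oracle_pred <- as.integer(g$datasets$a$x[, 1] > 0)
  ba <- balanced_accuracy(g$datasets$a$y, oracle_pred)
  expect_lt(abs(ba - bayes_accuracy(cfg)), 0.02)
})

test_that("learned models cannot beat the oracle ceiling materially", {
  ceiling_hits <- 0L
  for (s in 1:3) {
    cfg <- sim_config(n_samples = 2000, layers = c(a = 10),
                      effects = list(main_effect("a", 1, 0.9, 0.1)),
                      seed = 30 + s)
    g <- simulate_omics(cfg)
    cv <- run_cv(g$datasets$a$x, g$datasets$a$y,
                 control = genn_control(demes = 2, pop_size = 100,
                                        generations = 10),
                 k = 3, seed = s)
    ba <- mean(vapply(cv$per_fold, `[[`, 0, "test_ba"))
    expect_lte(ba, bayes_accuracy(cfg) + 0.05)
  }
})
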