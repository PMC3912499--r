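test_that("intermediate models are the per-generation per-deme bests", {
  dat <- make_threshold_data(n = 80, p = 5, seed = 4)
  ctl <- genn_control(demes = 3, pop_size = 30, generations = 6)
  s <- run_search(dat$x, dat$y, control = ctl, seed = 2)
  models <- collect_intermediate_models(s)
  expect_length(models, 3L * 6L)
  for (m in models) expect_s3_class(m, "genn_network")
  # two folds' searches pool their logs
  s2 <- run_search(dat$x, dat$y, control = ctl, seed = 5)
  expect_length(collect_intermediate_models(list(s, s2)), 36L)
})

test_that("variable frequencies use set semantics and rank all variables", {
  mk <- function(expr) parse_network(expr)
  models <- list(mk("PADD(1.0*V1,1.0*V2)"),
                 mk("PMULT(1.0*V1,2.0*V1)"),   # V1 twice counts once
                 mk("PADD(1.0*V1,1.0*V3)"),
                 mk("PSUB(1.0*V2,1.0*V2)"))
  tab <- variable_frequency(models, all_variables = paste0("V", 1:5))
  expect_equal(tab$frequency[tab$variable == "V1"], 0.75)
  expect_equal(tab$frequency[tab$variable == "V2"], 0.5)
  expect_equal(tab$frequency[tab$variable == "V4"], 0)
  expect_identical(tab$variable[1], "V1")
  expect_identical(attr(tab, "n_models"), 4L)
  # never-seen variables get the worst ranks, in input order
  expect_identical(tab$variable[4:5], c("V4", "V5"))
})

test_that("threshold retention uses the ceiling rule", {
  tab <- variable_frequency(list(parse_network("PADD(1.0*V1,1.0*V2)")),
                            all_variables = paste0("V", 1:20))
  expect_length(apply_threshold(tab, 0.10), 2L)
  tab54 <- variable_frequency(list(parse_network("PADD(1.0*V1,1.0*V2)")),
                              all_variables = paste0("V", 1:54))
  expect_length(apply_threshold(tab54, 0.50), 27L)
  expect_length(apply_threshold(tab54, 1.0), 54L)
  expect_length(apply_threshold(tab54, 0.001), 1L)  # ceil keeps at least one
})

test_that("retained sets are nested across increasing fractions", {
  dat <- make_threshold_data(n = 60, p = 12, seed = 10)
  tab <- genn_filter(dat$x, dat$y,
                     control = genn_control(demes = 2, pop_size = 40,
                                            generations = 5, migrations = 1),
                     seed = 4)
  fracs <- c(0.1, 0.25, 0.5, 0.75, 1.0)
  sets <- lapply(fracs, function(f) apply_threshold(tab, f))
  for (i in seq_len(length(fracs) - 1)) {
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
  }
})

test_that("filtering ranks a strong main effect first", {
  set.seed(1)
  sim <- simulate_omics(sim_config(n_samples = 300, layers = c(g = 30),
                                   effects = list(main_effect("g", 3)),
                                   seed = 11))
  d <- sim$datasets$g
  tab <- genn_filter(d$x, d$y,
                     control = genn_control(demes = 4, pop_size = 200,
                                            generations = 10, migrations = 1),
                     seed = 2)
  expect_lte(tab$rank[tab$variable == "g_f003"], 3L)
})

test_that("threshold selection returns its only candidate and is seeded", {
  dat <- make_threshold_data(n = 80, p = 6, seed = 12)
  small <- genn_control(demes = 1, pop_size = 30, generations = 3)
  res <- select_filter_threshold(dat$x, dat$y, candidate_fractions = 0.5,
                                 eval_control = small, filter_control = small,
                                 k = 4, seed = 9)
  expect_identical(res$best_fraction, 0.5)
  res2 <- select_filter_threshold(dat$x, dat$y, candidate_fractions = 0.5,
                                  eval_control = small, filter_control = small,
                                  k = 4, seed = 9)
  expect_identical(res$results, res2$results)
})
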