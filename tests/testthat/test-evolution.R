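test_that("migration interval is the generations/migrations quotient", {
  expect_identical(migration_interval(300, 15), 20L)
  expect_identical(migration_interval(20, 1), 20L)
  expect_identical(migration_interval(10, 20), 1L)   # clamped
  expect_true(is.na(migration_interval(50, 0)))      # never fires
})

test_that("initial demes are valid, reproducible, and stream-independent", {
  g <- genn_grammar()
  ctl <- genn_control(demes = 3, pop_size = 30)
  demes <- initialize_demes(g, 8, ctl, seed = 7)
  expect_length(demes, 3L)
  for (d in demes) {
    expect_length(d, 30L)
    for (genome in d) expect_true(map_genome(genome, g, 8)$valid)
  }
  expect_identical(demes, initialize_demes(g, 8, ctl, seed = 7))
  # growing the deme count leaves earlier demes' populations unchanged
  more <- initialize_demes(g, 8, genn_control(demes = 5, pop_size = 30), seed = 7)
  expect_identical(more[1:3], demes)
})

test_that("no variation plus full elitism is a fixed point", {
  g <- genn_grammar()
  dat <- make_threshold_data(n = 60, p = 4)
  ctl <- genn_control(demes = 1, pop_size = 20, p_crossover = 0,
                      p_mutation = 0, elitism = 20L)
  deme <- initialize_demes(g, 4, ctl, seed = 3)[[1]]
  stepped <- step_generation(deme, dat$x, dat$y, ctl, g, seed = 5)
  # same multiset of genomes (elites are emitted in fitness order)
  expect_identical(sort(vapply(stepped$genomes, paste, "", collapse = ",")),
                   sort(vapply(deme, paste, "", collapse = ",")))
})

test_that("high mutation makes non-elite offspring differ from parents", {
  g <- genn_grammar()
  dat <- make_threshold_data(n = 40, p = 4)
  ctl <- genn_control(demes = 1, pop_size = 30, p_crossover = 0,
                      p_mutation = 1, elitism = 1L)
  deme <- initialize_demes(g, 4, ctl, seed = 9)[[1]]
  stepped <- step_generation(deme, dat$x, dat$y, ctl, g, seed = 2)
  parents <- vapply(deme, paste, "", collapse = ",")
  children <- vapply(stepped$genomes, paste, "", collapse = ",")
  # all but the elite copy should be new genomes
  expect_gte(sum(!children %in% parents), 28L)
})

test_that("ring migration swaps bests, preserves sizes, never loses the best", {
  demes <- list(list(c(1L, 2L), c(3L, 4L), c(5L, 6L)),
                list(c(7L, 8L), c(9L, 10L), c(11L, 12L)))
  fitness <- list(c(0.9, 0.1, 0.5), c(0.2, 0.8, 0.4))
  out <- migrate(demes, fitness)
  expect_length(out[[1]], 3L)
  expect_length(out[[2]], 3L)
  # deme 2's best (0.8 -> genome 9,10) replaces deme 1's worst (index 2)
  expect_identical(out[[1]][[2]], c(9L, 10L))
  # deme 1's best (0.9 -> genome 1,2) replaces deme 2's worst (index 1)
  expect_identical(out[[2]][[1]], c(1L, 2L))
  # single deme: no-op
  expect_identical(migrate(demes[1], fitness[1]), demes[1])
})

test_that("search is seed-stable and its best dominates the log", {
  dat <- make_threshold_data(n = 120, p = 6)
  ctl <- genn_control(demes = 2, pop_size = 60, generations = 10)
  s1 <- run_search(dat$x, dat$y, control = ctl, seed = 42)
  s2 <- run_search(dat$x, dat$y, control = ctl, seed = 42)
  expect_identical(s1$log, s2$log)
  expect_identical(s1$best$expression, s2$best$expression)
  expect_gte(s1$best$fitness, max(s1$log$fitness))
})

test_that("per-deme best fitness is non-decreasing under elitism", {
  dat <- make_threshold_data(n = 100, p = 5, seed = 2)
  ctl <- genn_control(demes = 2, pop_size = 50, generations = 15)
  s <- run_search(dat$x, dat$y, control = ctl, seed = 8)
  for (d in unique(s$log$deme)) {
    f <- s$log$fitness[s$log$deme == d]
    expect_true(all(diff(f) >= 0))
  }
})

test_that("search finds a strong single-variable threshold signal", {
  set.seed(77)
  x <- matrix(rnorm(500 * 10), 500, 10)
  colnames(x) <- paste0("f", 1:10)
  y <- as.integer(x[, 1] > 0)
  wins <- 0L
  for (s in 1:2) {
    sr <- run_search(x, y, control = genn_control(demes = 2, pop_size = 200,
                                                  generations = 30), seed = s)
    if ("f1" %in% model_variables(sr$best$model) && sr$best$fitness >= 0.95)
      wins <- wins + 1L
  }
  expect_identical(wins, 2L)
})

test_that("degenerate one-class training data is rejected", {
  x <- matrix(rnorm(40), 20, 2)
  expect_error(run_search(x, rep(1L, 20)), "both classes")
})
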