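test_that("stratified folds reproduce the 258-sample split", {
  ids <- paste0("p", 1:258)
  labels <- c(rep(1L, 110), rep(0L, 148))
  fold <- split_folds(ids, labels, k = 5, seed = 1)
  sizes <- as.integer(table(fold))
  expect_identical(sort(sizes, decreasing = TRUE), c(52L, 52L, 52L, 51L, 51L))
  # 110 short-term samples stratify to exactly 22 per fold
  short_per_fold <- table(fold[labels == 1L])
  expect_true(all(short_per_fold == 22L))
  expect_identical(fold, split_folds(ids, labels, k = 5, seed = 1))
  expect_false(identical(fold, split_folds(ids, labels, k = 5, seed = 2)))
})

test_that("fold sizes and class proportions stay within one sample", {
  set.seed(30)
  for (i in 1:20) {
    n1 <- sample(10:40, 1); n0 <- sample(10:40, 1); k <- sample(2:5, 1)
    labels <- sample(c(rep(1L, n1), rep(0L, n0)))
    fold <- split_folds(seq_along(labels), labels, k = k, seed = i)
    expect_lte(diff(range(table(factor(fold, levels = 1:k)))), 1)
    expect_lte(diff(range(table(factor(fold[labels == 1], levels = 1:k)))), 1)
  }
})

test_that("a class smaller than k is rejected", {
  expect_error(split_folds(1:10, c(rep(0, 7), rep(1, 3)), k = 5),
               "at least k samples")
})

test_that("best-model selection follows frequency then accuracy then size", {
  mk <- function(expr, vars = NULL) {
    m <- parse_network(expr)
    if (!is.null(vars)) m$var_names <- vars
    m
  }
  # majority variable set {V1,V2} wins regardless of accuracy
  models <- list(mk("PADD(1.0*V1,1.0*V2)"), mk("PSUB(2.0*V1,0.1*V2)"),
                 mk("PADD(1.0*V3,1.0*V3)"), mk("PMULT(1.0*V1,1.0*V2)"),
                 mk("PADD(1.0*V4,1.0*V5)"))
  sel <- select_best_model(models, test_ba = c(.5, .9, .99, .6, .99))
  expect_setequal(model_variables(sel), c("V1", "V2"))
  expect_identical(format(sel), "PSUB(2.0*V1,0.1*V2)")  # best of its group
  # all distinct: highest test accuracy wins
  distinct <- list(mk("PADD(1.0*V1,1.0*V1)"), mk("PADD(1.0*V2,1.0*V2)"),
                   mk("PADD(1.0*V3,1.0*V3)"))
  expect_identical(model_variables(select_best_model(distinct, c(.6, .8, .7))),
                   "V2")
  # 2-2 frequency tie: higher mean test accuracy wins
  tied <- list(mk("PADD(1.0*V1,1.0*V1)"), mk("PSUB(1.0*V1,2.0*V1)"),
               mk("PADD(1.0*V2,1.0*V2)"), mk("PSUB(3.0*V2,1.0*V2)"))
  sel <- select_best_model(tied, test_ba = c(.70, .70, .65, .65))
  expect_identical(model_variables(sel), "V1")
})

test_that("variable consistency counts folds containing each variable", {
  mk <- function(expr) parse_network(expr)
  models <- list(mk("PADD(1.0*V1,1.0*V2)"), mk("PADD(1.0*V1,1.0*V1)"),
                 mk("PADD(1.0*V1,1.0*V3)"), mk("PADD(1.0*V2,1.0*V2)"),
                 mk("PADD(1.0*V1,1.0*V1)"))
  cons <- variable_consistency(models)
  expect_identical(cons[["V1"]], 4L)
  expect_identical(cons[["V2"]], 2L)
  expect_identical(cons[["V3"]], 1L)
  expect_false("V4" %in% names(cons))
})

test_that("cross-validation is structurally sound and leakage-free", {
  dat <- make_threshold_data(n = 150, p = 8, seed = 6)
  ctl <- genn_control(demes = 2, pop_size = 80, generations = 8)
  cv <- run_cv(dat$x, dat$y, control = ctl, k = 5, seed = 3)
  expect_length(cv$per_fold, 5L)
  for (f in seq_len(5)) {
    pf <- cv$per_fold[[f]]
    expect_gte(pf$test_ba, 0)
    expect_lte(pf$test_ba, 1)
  }
  # folds partition the samples
  expect_setequal(names(cv$folds), rownames(dat$x))
  expect_true(all(cv$folds %in% 1:5))
  # selected model's variable set appears among the fold-best models
  sel_vars <- sort(model_variables(cv$selected_model))
  fold_sets <- lapply(cv$per_fold, function(pf)
    sort(model_variables(pf$model)))
  expect_true(any(vapply(fold_sets, identical, TRUE, sel_vars)))
  # reproducibility of the whole protocol
  cv2 <- run_cv(dat$x, dat$y, control = ctl, k = 5, seed = 3)
  expect_identical(format(cv2$selected_model), format(cv$selected_model))
  expect_equal(vapply(cv2$per_fold, `[[`, 0, "test_ba"),
               vapply(cv$per_fold, `[[`, 0, "test_ba"))
})

test_that("fold searches never see their held-out samples", {
  # instrument by construction: plant the signal only in the held-out fold of
  # interest; a leakage-free search cannot learn it from training folds where
  # the feature is pure noise relative to y
  set.seed(99)
  n <- 100
  x <- matrix(rnorm(n * 3), n, 3)
  colnames(x) <- c("a", "b", "c")
  rownames(x) <- paste0("s", 1:n)
  y <- sample(0:1, n, replace = TRUE)
  y[c(0L, 1L) %in% 0:1] <- y  # keep both classes
  folds <- split_folds(rownames(x), y, k = 4, seed = 1)
  cv <- run_cv(x, y, control = genn_control(demes = 1, pop_size = 40,
                                            generations = 4),
               k = 4, seed = 1, folds = folds)
  # null data: test accuracies should hover near chance, not near 1
  ba <- vapply(cv$per_fold, `[[`, 0, "test_ba")
  expect_lt(mean(ba), 0.75)
})
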