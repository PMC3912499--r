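test_that("default grammar is fixed, complete, and finitely derivable", {
  g1 <- genn_grammar()
  g2 <- genn_grammar()
  expect_identical(g1, g2)
  terms <- unlist(g1$rules)
  expect_true(all(c("PADD", "PSUB", "PMULT", "PDIV") %in% terms))
  # choosing the first alternative everywhere terminates: the all-zero genome
  # must decode to a finite network
  m <- map_genome(rep(0L, 40L), g1, n_variables = 3)
  expect_true(m$valid)
  expect_identical(m$expression, "PADD(0.0*V1,0.0*V1)")
})

test_that("production choice follows the codon modulo rule", {
  expect_identical(choose_production(7, 4), 3L)
  expect_identical(choose_production(0, 3), 0L)
  expect_identical(choose_production(255, 2), 1L)
  expect_error(choose_production(5, 0))
})

test_that("a hand-constructed codon sequence decodes to PADD(1.0*V1,1.0*V2)", {
  # arity, op, then per input: sign, digit, digit, var-vs-node, two var codons
  codons <- c(0L, 0L,  0L, 1L, 0L, 0L, 0L, 0L,  0L, 1L, 0L, 0L, 0L, 1L)
  m <- map_genome(codons, genn_grammar(), n_variables = 2)
  expect_true(m$valid)
  expect_identical(m$expression, "PADD(1.0*V1,1.0*V2)")
  expect_identical(m$codons_used, 14L)
  expect_identical(m$wraps_used, 0L)
})

test_that("mapping is deterministic and neutral to trailing codons", {
  g <- genn_grammar()
  set.seed(11)
  for (i in 1:25) {
    genome <- random_genome()
    m1 <- map_genome(genome, g, n_variables = 7)
    m2 <- map_genome(genome, g, n_variables = 7)
    expect_identical(m1[c("valid", "expression", "codons_used", "wraps_used")],
                     m2[c("valid", "expression", "codons_used", "wraps_used")])
    if (m1$valid && m1$wraps_used == 0L) {
      extended <- c(genome, sample(0:255, 10, replace = TRUE))
      expect_identical(map_genome(extended, g, 7)$expression, m1$expression)
    }
  }
})

test_that("wrap exhaustion yields an invalid mapping, not an error", {
  # a single codon repeatedly selects the recursive path too often to finish
  m <- map_genome(1L, genn_grammar(), n_variables = 2, max_wraps = 2L)
  expect_false(m$valid)
  expect_null(m$model)
  expect_lte(m$wraps_used, 2L)
})

test_that("random functional genomes always map to valid networks", {
  g <- genn_grammar()
  for (i in 1:40) {
    genome <- random_functional_genome(g, n_variables = 12, max_depth = 10,
                                       seed = i)
    m <- map_genome(genome, g, 12)
    expect_true(m$valid)
    expect_identical(m$wraps_used, 0L)
    # mapping reproduces exactly the derivation that was grown
    expect_identical(m$expression, attr(genome, "expression"))
  }
  expect_identical(
    as.integer(random_functional_genome(g, 5, seed = 99)),
    as.integer(random_functional_genome(g, 5, seed = 99)))
})

test_that("depth budget bounds the grown network depth", {
  g <- genn_grammar()
  for (i in 1:20) {
    genome <- random_functional_genome(g, n_variables = 4, max_depth = 7,
                                       seed = 200 + i)
    m <- map_genome(genome, g, 4)
    expect_lte(gennet:::network_depth(m$model), 7L)
  }
})

test_that("grammars round-trip through plain-text BNF", {
  g <- genn_grammar()
  path <- withr::local_tempfile(fileext = ".bnf")
  write_grammar(g, path)
  g2 <- read_grammar(path)
  expect_identical(g2$start, g$start)
  expect_identical(g2$rules, g$rules)
  # a substituted grammar is usable for mapping
  m <- map_genome(rep(0L, 30L), g2, n_variables = 2)
  expect_true(m$valid)
})

test_that("malformed BNF is rejected", {
  path <- withr::local_tempfile(fileext = ".bnf")
  writeLines("network = <node>", path)
  expect_error(read_grammar(path), "malformed")
  writeLines("<network> ::= <nodes>", path)
  expect_error(read_grammar(path), "undefined non-terminal")
})
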