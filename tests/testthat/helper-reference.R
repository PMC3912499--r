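# Independent reference implementations used as oracles. These share no code
# with the package internals: the decoder is a naive recursive interpreter of
# the grammar object, the signed-rank oracle enumerates sign patterns by bit
# arithmetic, and the balanced-accuracy recount works from raw vectors.

# Naive recursive genotype->phenotype decoder. Returns the expression string,
# or NULL when the wrap budget is exhausted.
ref_decode <- function(codons, grammar, n_variables, max_wraps = 2L) {
  pos <- 0L
  wraps <- 0L
  failed <- FALSE
  next_codon <- function() {
    if (pos >= length(codons)) {
      if (wraps >= max_wraps) {
        failed <<- TRUE
        return(0L)
      }
      wraps <<- wraps + 1L
      pos <<- 0L
    }
    pos <<- pos + 1L
    codons[[pos]]
  }
  expand <- function(sym) {
    if (failed) return("")
    if (startsWith(sym, "<")) {
      rn <- substring(sym, 2L, nchar(sym) - 1L)
      alts <- grammar$rules[[rn]]
      a <- if (length(alts) > 1L) (next_codon() %% length(alts)) + 1L else 1L
      if (failed) return("")
      paste(vapply(alts[[a]], expand, ""), collapse = "")
    } else if (sym == "%var%") {
      c1 <- next_codon()
      c2 <- next_codon()
      if (failed) return("")
      paste0("V", ((c1 * 256L + c2) %% n_variables) + 1L)
    } else {
      sym
    }
  }
  s <- expand(paste0("<", grammar$start, ">"))
  if (failed) NULL else s
}

# Brute-force balanced accuracy from raw vectors.
ref_balanced_accuracy <- function(truth, pred) {
  sens <- mean(pred[truth == 1] == 1)
  spec <- mean(pred[truth == 0] == 0)
  (sens + spec) / 2
}

# Exact signed-rank p-value by bitwise enumeration of sign patterns.
ref_wilcoxon <- function(a, b, sides = "two") {
  d <- a - b
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) return(1.0)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  Wnull <- vapply(0:(2^m - 1), function(s) {
    sum(r[bitwAnd(s, 2^(seq_len(m) - 1)) > 0])
  }, 0)
  eps <- 1e-9
  p_ge <- mean(Wnull >= W - eps)
  if (sides == "one") return(p_ge)
  p_le <- mean(Wnull <= W + eps)
  min(1, 2 * min(p_ge, p_le))
}

# Small labelled matrix with a deterministic single-variable signal.
make_threshold_data <- function(n = 200, p = 10, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  colnames(x) <- paste0("f", seq_len(p))
  rownames(x) <- paste0("s", seq_len(n))
  list(x = x, y = as.integer(x[, 1] > 0))
}

random_genome <- function(len_range = c(5L, 60L)) {
  len <- sample(len_range[1]:len_range[2], 1L)
  sample(0:255, len, replace = TRUE)
}
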