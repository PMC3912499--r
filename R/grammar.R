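#' Construct the default network grammar
#'
#' Builds the fixed BNF grammar whose derivations are weighted activation-node
#' networks. A network is a tree of operator nodes (\code{PADD}, \code{PSUB},
#' \code{PMULT}, \code{PDIV}), each applied to 2 or 3 weighted inputs; an input
#' is either an input variable or a nested node; weights are signed decimals of
#' the form \code{d.d} (so -9.9 to 9.9 in steps of 0.1).
#'
#' Non-terminals are written \code{<name>}; the special terminal \code{\%var\%}
#' stands for "one input variable", whose concrete index is chosen at mapping
#' time from two codons: \code{index = (256*c1 + c2) mod p} for a dataset with
#' \code{p} variables (two codons so that layers with more than 256 features,
#' such as a genome-wide methylation array, remain fully addressable).
#'
#' The first alternative of every recursive rule is non-recursive, so both
#' depth-limited random growth and wrap-limited mapping always terminate.
#'
#' @return An object of class \code{genn_grammar}.
#' @examples
#' g <- genn_grammar()
#' print(g)
#' @export
genn_grammar <- function() {
  rules <- list(
    network = list(c("<node>")),
    node    = list(c("<op>", "(", "<winput>", ",", "<winput>", ")"),
                   c("<op>", "(", "<winput>", ",", "<winput>", ",", "<winput>", ")")),
    winput  = list(c("<weight>", "*", "<input>")),
    input   = list(c("%var%"), c("<node>")),
    op      = list("PADD", "PSUB", "PMULT", "PDIV"),
    weight  = list(c("<digit>", ".", "<digit>"), c("-", "<digit>", ".", "<digit>")),
    digit   = list("0", "1", "2", "3", "4", "5", "6", "7", "8", "9")
  )
  new_grammar(rules, start = "network")
}

new_grammar <- function(rules, start) {
  g <- structure(list(rules = rules, start = start), class = "genn_grammar")
  validate_grammar(g)
  g
}

is_nonterminal <- function(sym) startsWith(sym, "<") & endsWith(sym, ">")
nt_name <- function(sym) substring(sym, 2L, nchar(sym) - 1L)

validate_grammar <- function(g) {
  stopifnot(is.list(g$rules), length(g$rules) >= 1L, g$start %in% names(g$rules))
  for (rn in names(g$rules)) {
    alts <- g$rules[[rn]]
    if (length(alts) < 1L)
      stop("grammar rule <", rn, "> has no alternatives")
    for (alt in alts) {
      for (sym in alt) {
        if (is_nonterminal(sym) && !(nt_name(sym) %in% names(g$rules)))
          stop("undefined non-terminal ", sym, " referenced in rule <", rn, ">")
      }
    }
  }
  md <- grammar_min_steps(g)
  if (any(!is.finite(md)))
    stop("grammar cannot derive a finite string from: ",
         paste(names(md)[!is.finite(md)], collapse = ", "))
  invisible(g)
}

# Minimum derivation steps (through non-terminal expansions) needed to reach an
# all-terminal string from each non-terminal; Inf marks inescapable recursion.
grammar_min_steps <- function(g) {
  md <- stats::setNames(rep(Inf, length(g$rules)), names(g$rules))
  repeat {
    changed <- FALSE
    for (rn in names(g$rules)) {
      best <- Inf
      for (alt in g$rules[[rn]]) {
        nts <- alt[is_nonterminal(alt)]
        cost <- if (length(nts) == 0L) 1 else 1 + max(md[nt_name(nts)])
        best <- min(best, cost)
      }
      if (best < md[[rn]]) { md[[rn]] <- best; changed <- TRUE }
    }
    if (!changed) break
  }
  md
}

#' @export
print.genn_grammar <- function(x, ...) {
  cat("Grammar for evolved networks (start symbol <", x$start, ">)\n", sep = "")
  for (rn in names(x$rules)) {
    alts <- vapply(x$rules[[rn]], paste, "", collapse = " ")
    cat(sprintf("  <%s> ::= %s\n", rn, paste(alts, collapse = " | ")))
  }
  invisible(x)
}

#' Read / write a grammar as plain-text BNF
#'
#' One rule per line, \code{::=} separating the non-terminal from its
#' alternatives, \code{|} between alternatives, symbols whitespace-separated.
#' The first rule is the start symbol. Lines starting with \code{#} and blank
#' lines are ignored.
#'
#' @param path file path.
#' @param grammar a \code{genn_grammar}.
#' @return \code{read_grammar} returns a \code{genn_grammar};
#'   \code{write_grammar} returns \code{path} invisibly.
#' @export
read_grammar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rules <- list(); start <- NULL
  for (ln in lines) {
    parts <- strsplit(ln, "::=", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) stop("malformed BNF line: ", ln)
    lhs <- trimws(parts[1L])
    if (!is_nonterminal(lhs)) stop("left-hand side must be <name>: ", ln)
    rn <- nt_name(lhs)
    alts <- strsplit(parts[2L], "|", fixed = TRUE)[[1L]]
    rules[[rn]] <- lapply(alts, function(a) {
      syms <- strsplit(trimws(a), "[[:space:]]+")[[1L]]
      if (length(syms) == 0L || !any(nzchar(syms)))
        stop("empty alternative in rule <", rn, ">")
      syms[nzchar(syms)]
    })
    if (is.null(start)) start <- rn
  }
  new_grammar(rules, start = start)
}

#' @rdname read_grammar
#' @export
write_grammar <- function(grammar, path) {
  stopifnot(inherits(grammar, "genn_grammar"))
  ord <- unique(c(grammar$start, names(grammar$rules)))
  lines <- vapply(ord, function(rn) {
    alts <- vapply(grammar$rules[[rn]], paste, "", collapse = " ")
    sprintf("<%s> ::= %s", rn, paste(alts, collapse = " | "))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Production choice by the codon modulo rule
#'
#' @param codon integer in \code{[0, 255]}.
#' @param n_alternatives number of alternatives of the rule (>= 1).
#' @return Zero-based index \code{codon \%\% n_alternatives}.
#' @export
choose_production <- function(codon, n_alternatives) {
  stopifnot(length(n_alternatives) == 1L, n_alternatives >= 1L,
            codon >= 0L, codon <= 255L)
  as.integer(codon) %% as.integer(n_alternatives)
}

# Encode a grammar for the C++ mapper: rules as lists of integer vectors,
# terminal k -> +k (1-based index into the terminal table), non-terminal j -> -j.
encode_grammar <- function(grammar, n_variables) {
  if (n_variables > 65536)
    stop("at most 65,536 input variables are addressable (two 8-bit codons)")
  nts <- names(grammar$rules)
  terms <- character(0)
  enc_rules <- lapply(grammar$rules, function(alts) {
    lapply(alts, function(alt) {
      vapply(alt, function(sym) {
        if (is_nonterminal(sym)) {
          -match(nt_name(sym), nts)
        } else {
          i <- match(sym, terms)
          if (is.na(i)) { terms <<- c(terms, sym); i <- length(terms) }
          i
        }
      }, 0L, USE.NAMES = FALSE)
    })
  })
  list(rules = enc_rules,
       start = match(grammar$start, nts),
       terminals = terms,
       var_terminal = match("%var%", terms, nomatch = 0L),
       n_variables = as.integer(n_variables))
}

#' Map a codon genome to a network (genotype-to-phenotype mapping)
#'
#' Performs the deterministic leftmost derivation of grammatical evolution:
#' starting from the grammar's start symbol, each non-terminal with two or more
#' alternatives consumes one codon and expands to alternative
#' \code{codon mod n_alternatives} (single-alternative rules consume no codon);
#' the variable terminal consumes two codons (see \code{\link{genn_grammar}}).
#' When codons run out the read position wraps to the start of the genome, at
#' most \code{max_wraps} times; an individual still holding non-terminals after
#' that is invalid.
#'
#' @param genome integer vector of codons in \code{[0, 255]}.
#' @param grammar a \code{genn_grammar}.
#' @param n_variables number of input variables available (\code{V1..Vp}).
#' @param max_wraps maximum number of wraps (default 2).
#' @return A list of class \code{genn_mapping} with elements \code{valid},
#'   \code{model} (a \code{genn_network}, or \code{NULL} when invalid),
#'   \code{expression} (canonical expression string or \code{NA}),
#'   \code{codons_used}, \code{wraps_used}.
#' @examples
#' g <- genn_grammar()
#' m <- map_genome(c(0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L, 1L, 0L, 0L, 1L), g, n_variables = 2)
#' m$expression  # "PADD(1.0*V1,1.0*V2)"
#' @export
map_genome <- function(genome, grammar, n_variables, max_wraps = 2L) {
  stopifnot(inherits(grammar, "genn_grammar"), n_variables >= 1L,
            length(genome) >= 1L, all(genome >= 0L & genome <= 255L))
  enc <- encode_grammar(grammar, n_variables)
  res <- cpp_map_genome(as.integer(genome), enc, as.integer(max_wraps))
  out <- list(valid = res$valid,
              model = NULL,
              expression = NA_character_,
              codons_used = res$codons_used,
              wraps_used = res$wraps_used)
  if (res$valid) {
    out$expression <- tokens_to_string(res$tokens, enc$terminals)
    out$model <- parse_network(out$expression)
  }
  class(out) <- "genn_mapping"
  out
}

# tokens: integer vector; >=1 terminal id, <= -1 variable index -(v)
tokens_to_string <- function(tokens, terminals) {
  parts <- ifelse(tokens > 0L, terminals[pmax(tokens, 1L)],
                  paste0("V", -tokens))
  paste(parts, collapse = "")
}

#' @export
print.genn_mapping <- function(x, ...) {
  if (x$valid) {
    cat("Valid mapping (", x$codons_used, " codons, ", x$wraps_used,
        " wraps):\n  ", x$expression, "\n", sep = "")
  } else {
    cat("Invalid mapping: non-terminals left after", x$wraps_used, "wraps\n")
  }
  invisible(x)
}

#' Generate a random genome guaranteed to map to a functional network
#'
#' Grows a random derivation tree under a depth budget (recursive rules may not
#' be entered once the remaining budget cannot terminate them) and emits, in
#' leftmost order, codons that reproduce exactly that derivation. The returned
#' genome therefore always maps to a valid network with zero wraps.
#'
#' @param grammar a \code{genn_grammar}.
#' @param n_variables number of input variables.
#' @param max_depth derivation-depth budget through recursive rules
#'   (default 10, giving networks of up to roughly 3 nested node levels).
#' @param seed optional integer; when given, the R random stream is locally
#'   seeded so identical seeds give identical genomes.
#' @return Integer vector of codons, with attribute \code{"expression"}
#'   holding the expression string of the grown derivation (mapping the
#'   genome reproduces it exactly).
#' @export
random_functional_genome <- function(grammar, n_variables, max_depth = 10L,
                                     seed = NULL) {
  stopifnot(inherits(grammar, "genn_grammar"), max_depth >= 1L, n_variables >= 1L)
  if (!is.null(seed)) return(with_seed(seed,
    random_functional_genome(grammar, n_variables, max_depth)))
  md <- grammar_min_steps(grammar)
  codons <- integer(0)
  expr_parts <- character(0)
  emit_alt_codon <- function(alt_idx, n_alts) {
    # random codon whose modulo selects alt_idx (0-based)
    reps <- seq.int(alt_idx, 255L, by = n_alts)
    codons[[length(codons) + 1L]] <<- if (length(reps) == 1L) reps else sample(reps, 1L)
  }
  emit_var_codons <- function() {
    v <- sample.int(n_variables, 1L) - 1L            # 0-based index
    u <- v + n_variables * (sample.int(max(1L, (65535L - v) %/% n_variables + 1L), 1L) - 1L)
    codons[[length(codons) + 1L]] <<- u %/% 256L
    codons[[length(codons) + 1L]] <<- u %% 256L
    expr_parts[[length(expr_parts) + 1L]] <<- paste0("V", v + 1L)
  }
  grow <- function(rule_name, budget) {
    alts <- grammar$rules[[rule_name]]
    feas <- vapply(alts, function(alt) {
      nts <- alt[is_nonterminal(alt)]
      length(nts) == 0L || max(md[nt_name(nts)]) <= budget - 1
    }, TRUE)
    if (!any(feas)) stop("depth budget cannot terminate rule <", rule_name, ">")
    choice <- if (sum(feas) == 1L) which(feas) else sample(which(feas), 1L)
    if (length(alts) > 1L) emit_alt_codon(choice - 1L, length(alts))
    for (sym in alts[[choice]]) {
      if (is_nonterminal(sym)) grow(nt_name(sym), budget - 1)
      else if (sym == "%var%") emit_var_codons()
      else expr_parts[[length(expr_parts) + 1L]] <<- sym
    }
  }
  grow(grammar$start, max_depth)
  structure(codons, expression = paste(expr_parts, collapse = ""))
}

# Locally seed the R RNG, restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Deterministic 31-bit sub-seed derivation (seed, stream index) -> int
derive_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) + 1
  i <- as.double(index) + 1
  as.integer((s * 16807 + i * 48271 + s * i) %% 2147483647)
}
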