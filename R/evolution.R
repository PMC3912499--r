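#' Search hyper-parameters
#'
#' Collects every knob of the island-model genetic algorithm. The published
#' cluster-scale configuration is 50 demes of 5,000 individuals, 300
#' generations and 15 migrations with crossover probability 0.9 and per-codon
#' mutation probability 0.01; the defaults here are a desk-scale analogue
#' (2 demes x 500, 50 generations) that keeps the same operator probabilities.
#'
#' @param demes number of island sub-populations.
#' @param pop_size individuals per deme.
#' @param generations number of generations.
#' @param migrations number of migration events spread evenly over the run
#'   (interval \code{floor(generations/migrations)}, clamped to at least 1);
#'   0 disables migration.
#' @param p_crossover probability of single-point crossover per offspring.
#' @param p_mutation per-codon probability of uniform codon resampling.
#' @param max_wraps genome wraps allowed during mapping; individuals that
#'   exhaust them are invalid and receive fitness 0.
#' @param max_init_depth derivation-depth budget of initial random networks.
#' @param tournament_size selection tournament size.
#' @param elitism individuals copied unchanged per deme per generation.
#' @param max_genome_length codon cap; crossover offspring are truncated.
#' @return A list of class \code{genn_control}.
#' @export
genn_control <- function(demes = 2L, pop_size = 500L, generations = 50L,
                         migrations = 2L, p_crossover = 0.9,
                         p_mutation = 0.01, max_wraps = 2L,
                         max_init_depth = 10L, tournament_size = 2L,
                         elitism = 1L, max_genome_length = 250L) {
  ctl <- list(demes = as.integer(demes), pop_size = as.integer(pop_size),
              generations = as.integer(generations),
              migrations = as.integer(migrations),
              p_crossover = p_crossover, p_mutation = p_mutation,
              max_wraps = as.integer(max_wraps),
              max_init_depth = as.integer(max_init_depth),
              tournament_size = as.integer(tournament_size),
              elitism = as.integer(elitism),
              max_genome_length = as.integer(max_genome_length))
  stopifnot(ctl$demes >= 1L, ctl$pop_size >= 1L, ctl$generations >= 1L,
            ctl$migrations >= 0L,
            ctl$p_crossover >= 0, ctl$p_crossover <= 1,
            ctl$p_mutation >= 0, ctl$p_mutation <= 1,
            ctl$max_wraps >= 0L, ctl$max_init_depth >= 1L,
            ctl$tournament_size >= 1L, ctl$elitism >= 0L,
            ctl$max_genome_length >= 1L)
  if (ctl$migrations > ctl$generations) ctl$migrations <- ctl$generations
  class(ctl) <- "genn_control"
  ctl
}

#' Search preset for marginal-free interaction discovery
#'
#' A \code{\link{genn_control}} tuned for finding pure interactions (e.g. a
#' cross-layer XOR) whose component variables carry no marginal signal. Such
#' signals give the search no gradient — a candidate model scores at chance
#' until it holds the complete interacting set — so the preset maximises the
#' rate at which distinct small candidate models are tried: genomes are kept
#' short (cap 40 codons, initial depth 7, which confines networks to a single
#' activation node over 2-3 variables, where a \code{PMULT}/\code{PDIV} node
#' expresses an XOR directly) and the per-codon mutation rate is raised to
#' 0.2 so each offspring resamples about one variable reference. Many demes
#' act as independent restarts.
#'
#' @param demes,pop_size,generations,migrations,p_mutation,max_init_depth,max_genome_length
#'   overridable preset values.
#' @param ... further arguments passed to \code{\link{genn_control}}.
#' @return A \code{genn_control}.
#' @export
genn_control_interaction <- function(demes = 10L, pop_size = 500L,
                                     generations = 60L, migrations = 2L,
                                     p_mutation = 0.2, max_init_depth = 7L,
                                     max_genome_length = 40L, ...) {
  genn_control(demes = demes, pop_size = pop_size, generations = generations,
               migrations = migrations, p_mutation = p_mutation,
               max_init_depth = max_init_depth,
               max_genome_length = max_genome_length, ...)
}

#' Generations between migration events
#'
#' @param n_generations total generations.
#' @param n_migrations number of migration events; 0 means never.
#' @return \code{floor(n_generations/n_migrations)}, clamped to at least 1;
#'   migration fires at positive multiples of the interval. Returns \code{NA}
#'   for \code{n_migrations = 0}.
#' @examples
#' migration_interval(300, 15)  # 20
#' @export
migration_interval <- function(n_generations, n_migrations) {
  stopifnot(n_generations >= 1, n_migrations >= 0)
  if (n_migrations == 0) return(NA_integer_)
  max(1L, as.integer(n_generations %/% n_migrations))
}

#' Initialize island sub-populations
#'
#' Every genome is produced by \code{\link{random_functional_genome}}, so all
#' initial individuals map to valid networks. Each deme draws from a random
#' stream derived deterministically from \code{seed} and its deme index, so a
#' deme's initial population does not change when more demes are added.
#'
#' @param grammar a \code{genn_grammar}.
#' @param n_variables number of input variables.
#' @param control a \code{\link{genn_control}}.
#' @param seed integer seed.
#' @return List (one element per deme) of lists of codon genomes.
#' @export
initialize_demes <- function(grammar, n_variables, control = genn_control(),
                             seed = 1L) {
  enc <- encode_grammar(grammar, n_variables)
  lapply(seq_len(control$demes) - 1L, function(d) {
    cpp_random_genomes(enc, control$pop_size, control$max_init_depth,
                       as.double(derive_seed(seed, d)))
  })
}

#' Advance one deme by one generation
#'
#' One step of the per-deme loop: the \code{elitism} best individuals are
#' copied unchanged; the rest are bred by tournament selection of two parents,
#' single-point crossover at codon boundaries (cut points independent per
#' parent) with probability \code{p_crossover}, and per-codon mutation, then
#' remapped and re-evaluated on the training data.
#'
#' @param deme list of codon genomes.
#' @param x training feature matrix (samples x features).
#' @param y training classes (0/1).
#' @param control a \code{\link{genn_control}}.
#' @param grammar a \code{genn_grammar}.
#' @param seed integer seed for the deme's stream.
#' @return List with \code{genomes}, \code{fitness}, and the generation's
#'   best-model log entry.
#' @export
step_generation <- function(deme, x, y, control = genn_control(),
                            grammar = genn_grammar(), seed = 1L) {
  enc <- encode_grammar(grammar, ncol(x))
  res <- cpp_evolve_deme(deme, as_feature_matrix(x), as_binary(y), enc,
                         1L, control$p_crossover, control$p_mutation,
                         control$tournament_size, control$elitism,
                         control$max_wraps, control$max_genome_length,
                         as.double(seed))
  list(genomes = res$genomes, fitness = as.numeric(res$fitness),
       log = res$log[[1L]])
}

as_feature_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("feature matrix contains non-finite values")
  x
}

#' Run the island-model search
#'
#' Initializes \code{demes} islands of functional genomes and evolves them for
#' \code{generations} generations; every \code{\link{migration_interval}}
#' generations a copy of each deme's best individual replaces the worst
#' individual of the next deme on a ring. Fitness is the balanced accuracy of
#' the decoded network's sign-threshold predictions on the training data;
#' invalid mappings receive fitness 0. Results are identical for identical
#' seeds because every deme owns its own random stream.
#'
#' @param x training feature matrix (samples x features); column names, when
#'   present, are bound to the returned models.
#' @param y training classes (0/1 or two-level factor); both classes required.
#' @param grammar a \code{genn_grammar}.
#' @param control a \code{\link{genn_control}}.
#' @param seed integer seed.
#' @param layers optional character vector (one per column of \code{x}) giving
#'   each feature's omics layer of origin.
#' @param cores demes are evolved in parallel with this many processes
#'   (\code{parallel::mclapply}); results are identical to serial execution
#'   because every deme owns its own random stream.
#' @return List of class \code{genn_search} with \code{best} (list:
#'   \code{model}, \code{fitness}, \code{genome}, \code{expression}),
#'   \code{log} (data.frame: generation, deme, fitness, nodes) and
#'   \code{log_models} (the per-generation per-deme best networks, as token
#'   vectors convertible by \code{\link{collect_intermediate_models}}).
#' @export
run_search <- function(x, y, grammar = genn_grammar(),
                       control = genn_control(), seed = 1L, layers = NULL,
                       cores = 1L) {
  x <- as_feature_matrix(x)
  y <- as_binary(y)
  if (length(unique(y)) < 2L)
    stop("training data must contain both classes")
  stopifnot(nrow(x) == length(y))
  enc <- encode_grammar(grammar, ncol(x))

  demes <- initialize_demes(grammar, ncol(x), control, seed)
  n_demes <- control$demes
  interval <- migration_interval(control$generations, control$migrations)
  # chunk boundaries: migrate after each full interval (never after the last
  # generation's chunk end == total, where migration would be unobservable)
  bounds <- if (is.na(interval)) control$generations else
    unique(c(seq.int(interval, control$generations, by = interval),
             control$generations))
  fitness <- vector("list", n_demes)
  logs <- vector("list", n_demes)           # per deme: list of gen entries
  for (d in seq_len(n_demes)) logs[[d]] <- vector("list", control$generations)

  gen_done <- 0L
  chunk_id <- 0L
  for (b in bounds) {
    ngen <- b - gen_done
    if (ngen > 0L) {
      evolve_one <- function(d) {
        cpp_evolve_deme(demes[[d]], x, y, enc, ngen,
                        control$p_crossover, control$p_mutation,
                        control$tournament_size, control$elitism,
                        control$max_wraps, control$max_genome_length,
                        as.double(derive_seed(seed, 1000L + 997L * d + chunk_id)))
      }
      # each deme owns its random stream, so parallel and serial execution
      # give identical results
      results <- if (cores > 1L)
        parallel::mclapply(seq_len(n_demes), evolve_one, mc.cores = cores)
      else lapply(seq_len(n_demes), evolve_one)
      for (d in seq_len(n_demes)) {
        res <- results[[d]]
        demes[[d]] <- res$genomes
        fitness[[d]] <- as.numeric(res$fitness)
        for (g in seq_len(ngen)) logs[[d]][[gen_done + g]] <- res$log[[g]]
      }
      gen_done <- b
      chunk_id <- chunk_id + 1L
    }
    if (gen_done < control$generations && n_demes >= 2L)
      demes <- migrate_ring(demes, fitness)
  }

  log_df <- do.call(rbind, lapply(seq_len(n_demes), function(d) {
    data.frame(generation = seq_len(control$generations), deme = d,
               fitness = vapply(logs[[d]], function(e) e$fitness, 0),
               nodes = vapply(logs[[d]], function(e) e$nodes, 0L))
  }))
  log_models <- lapply(seq_len(n_demes), function(d)
    lapply(logs[[d]], function(e) e$tokens))

  best_row <- which.max(log_df$fitness)
  bd <- log_df$deme[best_row]; bg <- log_df$generation[best_row]
  best_tokens <- logs[[bd]][[bg]]$tokens
  model <- network_from_tokens(best_tokens, enc$terminals,
                               var_names = colnames(x), var_layers = layers)
  structure(list(
    best = list(model = model,
                fitness = log_df$fitness[best_row],
                expression = format(model)),
    log = log_df,
    log_models = log_models,
    terminals = enc$terminals,
    var_names = colnames(x),
    var_layers = layers,
    control = control, seed = seed), class = "genn_search")
}

# Ring migration: deme i's best replaces deme (i+1)'s worst, simultaneously.
migrate_ring <- function(demes, fitness) {
  n <- length(demes)
  if (n < 2L) return(demes)
  bests <- lapply(seq_len(n), function(d) demes[[d]][[which.max(fitness[[d]])]])
  for (d in seq_len(n)) {
    src <- if (d == 1L) n else d - 1L
    worst <- which.min(fitness[[d]])
    demes[[d]][[worst]] <- bests[[src]]
  }
  demes
}

#' Migrate best individuals between demes (ring topology)
#'
#' A copy of each deme's best individual replaces the worst individual of the
#' next deme (\code{i -> (i + 1) mod n}), simultaneously for all demes; a
#' single deme is returned unchanged. Population sizes are preserved and the
#' global best fitness can only stay or improve.
#'
#' @param demes list of demes (each a list of genomes).
#' @param fitness list of per-deme fitness vectors aligned with \code{demes}.
#' @return The migrated demes.
#' @export
migrate <- function(demes, fitness) {
  stopifnot(length(demes) == length(fitness))
  migrate_ring(demes, fitness)
}

#' @export
print.genn_search <- function(x, ...) {
  cat("Island-model search:", x$control$demes, "demes x", x$control$pop_size,
      "individuals,", x$control$generations, "generations\n")
  cat("Best training balanced accuracy:", sprintf("%.4f", x$best$fitness), "\n")
  cat("Best model:", x$best$expression, "\n")
  invisible(x)
}
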