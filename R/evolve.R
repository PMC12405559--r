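#' Evolutionary design-loop configuration
#'
#' Hyperparameters of the elitist evolutionary hallucination loop. The
#' defaults follow the published design runs: population size 10,
#' suboptimality 0.1 (parents within 10% of the best fitness are
#' eligible for reproduction), cysteine-free alphabet, and around one
#' point substitution per child.
#'
#' @param population_size Pool size (>= 1, default 10).
#' @param suboptimality Eligibility band as a fraction of the best
#'   fitness, in \[0, 1\] (default 0.1); 0 restricts parenthood to the
#'   current best members.
#' @param mutation_rate Expected substitutions per child (> 0; children
#'   always differ from their parent in at least one position).
#' @param alphabet Allowed residues (default [AA_DESIGN], no cysteine).
#' @param fitness_threshold Stop once any pool member reaches this
#'   fitness (default `Inf`, i.e. run to budget).
#' @param max_evaluations Oracle-evaluation budget (default 2000).
#' @param children_per_step Candidates proposed per step (default:
#'   `population_size`).
#' @param seed RNG seed for the run (init, mutation and selection draw
#'   from one seeded stream so runs are reproducible bit-for-bit).
#' @return Object of class `evolve_config`.
#' @export
evolve_config <- function(population_size = 10L, suboptimality = 0.1,
                          mutation_rate = 1, alphabet = AA_DESIGN,
                          fitness_threshold = Inf, max_evaluations = 2000L,
                          children_per_step = population_size, seed = 1L) {
  if (population_size < 1L) pd_stop("invalid_config", "population_size must be >= 1")
  if (suboptimality < 0 || suboptimality > 1)
    pd_stop("invalid_config", "suboptimality outside [0, 1]")
  if (mutation_rate <= 0) pd_stop("invalid_config", "mutation_rate must be > 0")
  if (!length(alphabet)) pd_stop("invalid_config", "empty alphabet")
  structure(list(population_size = as.integer(population_size),
                 suboptimality = suboptimality, mutation_rate = mutation_rate,
                 alphabet = alphabet, fitness_threshold = fitness_threshold,
                 max_evaluations = as.integer(max_evaluations),
                 children_per_step = as.integer(children_per_step),
                 seed = as.integer(seed)),
            class = "evolve_config")
}

# Sequences are carried internally as single strings with "/" separating
# chains; helpers convert to chained_seq for oracle calls.
split_chains <- function(s) strsplit(s, "/", fixed = TRUE)[[1]]

#' Initialise a design pool
#'
#' Draws `population_size` sequences with residues i.i.d. uniform over
#' the allowed alphabet, evaluates them, and returns the initial pool
#' state. Deterministic given the config seed.
#'
#' @param cfg An [evolve_config()].
#' @param lengths Integer vector of per-chain lengths (a single integer
#'   for monomer design).
#' @param evaluate Evaluator function: takes a character vector of
#'   `"/"`-separated chain sequences, returns a list with `fitness`
#'   (numeric vector) and optionally `predictions` (list). See
#'   [oracle_evaluator()].
#' @return Object of class `pool_state`.
#' @export
init_pool <- function(cfg, lengths, evaluate) {
  stopifnot(inherits(cfg, "evolve_config"), all(lengths >= 1L))
  seqs <- with_local_seed(cfg$seed, {
    vapply(seq_len(cfg$population_size), function(i) {
      paste(vapply(lengths, function(l)
        paste(sample(cfg$alphabet, l, replace = TRUE), collapse = ""), ""),
        collapse = "/")
    }, "")
  })
  state <- structure(list(members = data.frame(sequence = seqs,
                                               fitness = NA_real_,
                                               generation = 0L,
                                               parent = NA_character_,
                                               stringsAsFactors = FALSE),
                          lengths = as.integer(lengths),
                          cache = new.env(parent = emptyenv()),
                          predictions = new.env(parent = emptyenv()),
                          eval_count = 0L, generation = 0L,
                          rng = cfg$seed + 1L,
                          best = NULL, trace = list()),
                     class = "pool_state")
  state <- evaluate_members(state, cfg, evaluate, seq_len(nrow(state$members)))
  state$best <- state$members[which.max(state$members$fitness), ]
  state
}

evaluate_members <- function(state, cfg, evaluate, rows) {
  seqs <- state$members$sequence[rows]
  cached <- vapply(seqs, function(s) !is.null(state$cache[[s]]), TRUE)
  todo <- unique(seqs[!cached])
  if (length(todo)) {
    if (state$eval_count + length(todo) > cfg$max_evaluations)
      todo <- todo[seq_len(max(cfg$max_evaluations - state$eval_count, 0L))]
    if (length(todo)) {
      res <- evaluate(todo)
      for (i in seq_along(todo)) {
        state$cache[[todo[i]]] <- res$fitness[i]
        if (!is.null(res$predictions))
          state$predictions[[todo[i]]] <- res$predictions[[i]]
      }
      state$eval_count <- state$eval_count + length(todo)
    }
  }
  state$members$fitness[rows] <- vapply(seqs, function(s)
    state$cache[[s]] %||% -Inf, 1)
  state
}

#' Propose mutated children from the current pool
#'
#' Parents are drawn uniformly from the eligible set -- members whose
#' fitness lies within the suboptimality band of the current best
#' (`fitness >= best - suboptimality * |best|`). Each child carries a
#' number of point substitutions distributed Poisson(`mutation_rate`)
#' conditioned on being at least 1, at positions drawn without
#' replacement, never re-introducing the parent residue or leaving the
#' alphabet.
#'
#' @param state A `pool_state`.
#' @param cfg An [evolve_config()].
#' @param n Number of children (default `cfg$children_per_step`).
#' @return Character vector of child sequences (with parent attribute).
#' @export
propose_children <- function(state, cfg, n = cfg$children_per_step) {
  stopifnot(inherits(state, "pool_state"))
  fit <- state$members$fitness
  best <- max(fit)
  eligible <- which(fit >= best - cfg$suboptimality * abs(best))
  pairs <- with_local_seed(state$rng, {
    lapply(seq_len(n), function(k) {
      parent <- state$members$sequence[eligible[sample.int(length(eligible), 1L)]]
      c(child = mutate_sequence(parent, cfg), parent = parent)
    })
  })
  out <- vapply(pairs, `[[`, "", "child")
  attr(out, "parents") <- vapply(pairs, `[[`, "", "parent")
  attr(out, "rng_next") <- state$rng + 1L
  out
}

mutate_sequence <- function(parent, cfg) {
  chains <- split_chains(parent)
  chars <- unlist(strsplit(chains, "", fixed = TRUE))
  n <- length(chars)
  k <- 0L
  while (k < 1L) k <- stats::rpois(1L, cfg$mutation_rate)
  k <- min(k, n)
  pos <- sample.int(n, k)
  for (p in pos) {
    choices <- setdiff(cfg$alphabet, chars[p])
    chars[p] <- choices[sample.int(length(choices), 1L)]
  }
  lens <- nchar(chains)
  paste(vapply(split(chars, rep(seq_along(lens), lens)), paste, "",
               collapse = ""), collapse = "/")
}

#' One elitist evolutionary step
#'
#' Proposes children, evaluates any not in the fitness cache, and keeps
#' the `population_size` fittest of parents and children combined
#' (deduplicated by sequence), so the best-so-far fitness never
#' decreases.
#'
#' @inheritParams propose_children
#' @param evaluate Evaluator as in [init_pool()].
#' @return Updated `pool_state`.
#' @export
evolve_step <- function(state, cfg, evaluate) {
  children <- propose_children(state, cfg)
  state$rng <- attr(children, "rng_next")
  gen <- state$generation + 1L
  pool <- rbind(state$members[, c("sequence", "fitness", "generation", "parent")],
                data.frame(sequence = as.character(children), fitness = NA_real_,
                           generation = gen, parent = NA_character_,
                           stringsAsFactors = FALSE))
  pool <- pool[!duplicated(pool$sequence), , drop = FALSE]
  state$members <- pool
  state <- evaluate_members(state, cfg, evaluate, seq_len(nrow(pool)))
  ord <- order(-state$members$fitness)
  state$members <- state$members[ord[seq_len(min(cfg$population_size,
                                                 length(ord)))], , drop = FALSE]
  rownames(state$members) <- NULL
  state$generation <- gen
  top <- state$members[1, ]
  if (is.null(state$best) || top$fitness >= state$best$fitness) state$best <- top
  state$trace[[gen]] <- data.frame(generation = gen,
                                   best_fitness = state$best$fitness,
                                   mean_fitness = mean(state$members$fitness),
                                   evaluations = state$eval_count)
  state
}

#' Run a design to threshold or budget
#'
#' Repeats [evolve_step()] until some pool member reaches the fitness
#' threshold or the evaluation budget is exhausted, then returns every
#' sequence at or above the threshold together with its cached
#' prediction, plus a reproducible run manifest (config, seed and
#' iteration trace). Budget exhaustion without success yields an empty
#' candidate set with status `"budget_exhausted"`, not an error.
#'
#' @param cfg An [evolve_config()] (threshold and budget set).
#' @param lengths Per-chain lengths.
#' @param evaluate Evaluator as in [init_pool()].
#' @return List with `candidates` (data.frame sequence/fitness),
#'   `predictions` (named list), `status`, `state` and `trace`.
#' @export
run_design <- function(cfg, lengths, evaluate) {
  state <- init_pool(cfg, lengths, evaluate)
  while (max(state$members$fitness) < cfg$fitness_threshold &&
         state$eval_count < cfg$max_evaluations) {
    state <- evolve_step(state, cfg, evaluate)
  }
  hits <- state$members[state$members$fitness >= cfg$fitness_threshold, ,
                        drop = FALSE]
  status <- if (nrow(hits)) "threshold_reached" else "budget_exhausted"
  preds <- stats::setNames(lapply(hits$sequence, function(s)
    state$predictions[[s]]), hits$sequence)
  trace <- if (length(state$trace)) do.call(rbind, state$trace) else
    data.frame(generation = integer(0), best_fitness = numeric(0),
               mean_fitness = numeric(0), evaluations = integer(0))
  list(candidates = hits, predictions = preds, status = status,
       state = state, trace = trace,
       manifest = list(config = unclass(cfg), lengths = lengths,
                       seed = cfg$seed, status = status,
                       evaluations = state$eval_count,
                       best_fitness = state$best$fitness))
}

#' Build an oracle-backed fitness evaluator
#'
#' Wraps a structure oracle and a [fitness_spec()] into the evaluator
#' closure consumed by the evolutionary loop: each sequence is turned
#' into an [oracle_request()] (attaching the target template for binder
#' tasks, and predicting the monomeric state as well for
#' conformational-change tasks), predicted, and scored with
#' [composite_fitness()].
#'
#' @param oracle A structure oracle (e.g. [synthetic_folder()]).
#' @param spec A [fitness_spec()].
#' @param chain_ids Chain ids of the designed sequence(s).
#' @param template Optional [pd_template()] for the fixed target chain
#'   (binder tasks); the target sequence is appended as its own chain.
#' @param target_chain_id Chain id given to the template chain.
#' @param recycles Recycling steps requested per prediction (default 2,
#'   the design-stage setting).
#' @return Function mapping a character vector of `"/"`-separated
#'   sequences to `list(fitness, predictions)`.
#' @export
oracle_evaluator <- function(oracle, spec, chain_ids = NULL, template = NULL,
                             target_chain_id = "T", recycles = 2L) {
  force(oracle); force(spec)
  function(seqs) {
    preds <- vector("list", length(seqs))
    fit <- numeric(length(seqs))
    for (i in seq_along(seqs)) {
      chains <- split_chains(seqs[i])
      ids <- chain_ids %||% LETTERS[seq_along(chains)]
      if (spec$task == "binder") {
        cs <- chained_seq(c(chains, template$sequence),
                          chain_ids = c(ids, target_chain_id))
        tpl <- stats::setNames(list(template), target_chain_id)
        cx <- predict_structure(oracle, oracle_request(cs, templates = tpl,
                                                       recycle_count = recycles))
        sp <- spec
        sp$designed <- sp$designed %||% ids
        sp$target <- target_chain_id
        fit[i] <- composite_fitness(sp, list(complex = cx))
        preds[[i]] <- cx
      } else if (spec$task == "change") {
        mono <- predict_structure(oracle, oracle_request(
          chained_seq(chains[1], chain_ids = ids[1]), recycle_count = recycles))
        cx <- predict_structure(oracle, oracle_request(
          chained_seq(chains, chain_ids = ids), recycle_count = recycles))
        fit[i] <- composite_fitness(spec, list(monomer = mono, complex = cx))
        preds[[i]] <- cx
      } else {
        cx <- predict_structure(oracle, oracle_request(
          chained_seq(chains, chain_ids = ids), recycle_count = recycles))
        fit[i] <- composite_fitness(spec, list(complex = cx))
        preds[[i]] <- cx
      }
    }
    list(fitness = fit, predictions = preds)
  }
}
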