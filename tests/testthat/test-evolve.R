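# evaluator over a plain scoring function (no oracle): fast test bed
fn_evaluator <- function(score) function(seqs) list(fitness = score(seqs))

test_that("pool initialisation is uniform over the alphabet and seeded", {
  cfg <- evolve_config(population_size = 50L, seed = 8L)
  ev <- fn_evaluator(function(s) nchar(s) * 0)
  pool1 <- init_pool(cfg, lengths = 200L, ev)
  pool2 <- init_pool(cfg, lengths = 200L, ev)
  expect_identical(pool1$members$sequence, pool2$members$sequence)

  chars <- unlist(strsplit(pool1$members$sequence, ""))
  expect_false(any(chars == "C"))          # cysteine-free design alphabet
  # 10,000 residues: each residue frequency within 3 sigma of 1/19
  tab <- table(factor(chars, levels = AA_DESIGN))
  p0 <- 1 / length(AA_DESIGN)
  sigma <- sqrt(p0 * (1 - p0) / length(chars))
  expect_true(all(abs(tab / length(chars) - p0) < 3 * sigma + 1e-9))

  expect_error(evolve_config(alphabet = character(0)), class = "invalid_config")
})

test_that("children are point mutants of eligible parents", {
  land <- toy_landscape()
  cfg <- evolve_config(population_size = 10L, mutation_rate = 1,
                       alphabet = land$alphabet, seed = 3L)
  pool <- init_pool(cfg, lengths = land$len, fn_evaluator(land$score))

  hamming <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  kids <- propose_children(pool, cfg, n = 500L)
  parents <- pool$members$sequence
  dists <- vapply(kids, function(k) min(vapply(parents, hamming, 1L, b = k)), 1L)
  expect_true(all(dists >= 1L))
  # substitution counts look like Poisson(1) conditioned on >= 1
  expected_mean <- 1 / (1 - exp(-1))
  expect_lt(abs(mean(dists) - expected_mean), 0.12)
  expect_false(any(grepl("[^AEKL]", kids)))   # alphabet closure

  # suboptimality 0: every child derives from a best-fitness parent
  cfg0 <- evolve_config(population_size = 10L, suboptimality = 0,
                        alphabet = land$alphabet, seed = 3L)
  pool0 <- init_pool(cfg0, lengths = land$len, fn_evaluator(land$score))
  best <- pool0$members$sequence[pool0$members$fitness ==
                                   max(pool0$members$fitness)]
  kids0 <- propose_children(pool0, cfg0, n = 200L)
  expect_true(all(attr(kids0, "parents") %in% best))
})

test_that("elitist steps never lose the best member and cache evaluations", {
  land <- toy_landscape()
  calls <- new.env(); calls$n <- 0L
  counting <- function(seqs) { calls$n <- calls$n + length(seqs)
                               list(fitness = land$score(seqs)) }
  cfg <- evolve_config(population_size = 8L, alphabet = land$alphabet,
                       seed = 5L, max_evaluations = 10000L)
  pool <- init_pool(cfg, lengths = land$len, counting)
  best_before <- max(pool$members$fitness)
  for (i in 1:30) {
    pool <- evolve_step(pool, cfg, counting)
    best_now <- max(pool$members$fitness)
    expect_gte(best_now, best_before)
    best_before <- best_now
  }
  # the fitness cache absorbs duplicate children: distinct evaluations only
  expect_equal(calls$n, pool$eval_count)
  expect_lte(pool$eval_count, 8L + 30L * 8L)
})

test_that("run_design terminates on threshold, budget, and vacuous thresholds", {
  land <- toy_landscape()
  ev <- fn_evaluator(land$score)
  # vacuous threshold: returns after the first evaluation round
  cfg <- evolve_config(population_size = 5L, alphabet = land$alphabet,
                       fitness_threshold = -Inf, seed = 2L)
  out <- run_design(cfg, land$len, ev)
  expect_equal(out$status, "threshold_reached")
  expect_equal(out$state$eval_count, 5L)

  # unattainable threshold on a bounded landscape: empty result, not an error
  cfg2 <- evolve_config(population_size = 5L, alphabet = land$alphabet,
                        fitness_threshold = land$optimum + 10,
                        max_evaluations = 60L, seed = 2L)
  out2 <- run_design(cfg2, land$len, ev)
  expect_equal(out2$status, "budget_exhausted")
  expect_equal(nrow(out2$candidates), 0L)

  # bit-reproducibility of a full run
  cfg3 <- evolve_config(population_size = 6L, alphabet = land$alphabet,
                        fitness_threshold = land$optimum * 0.95,
                        max_evaluations = 500L, seed = 11L)
  r1 <- run_design(cfg3, land$len, ev)
  r2 <- run_design(cfg3, land$len, ev)
  expect_identical(r1$candidates, r2$candidates)
  expect_identical(r1$trace, r2$trace)
})

test_that("the loop recovers the exhaustively known optimum on a toy landscape", {
  land <- toy_landscape()
  hits <- 0L
  for (seed in 1:10) {
    cfg <- evolve_config(population_size = 10L, suboptimality = 0.1,
                         alphabet = land$alphabet,
                         fitness_threshold = (1 - 0.1) * land$optimum,
                         max_evaluations = 2000L, seed = seed)
    out <- run_design(cfg, land$len, fn_evaluator(land$score))
    if (out$status == "threshold_reached" &&
        max(out$candidates$fitness) >= (1 - 0.1) * land$optimum) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})
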