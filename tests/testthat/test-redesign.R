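# fixed-matrix toy models
matrix_model <- function(mat) {
  colnames(mat) <- colnames(mat) %||% AA_STANDARD
  sequence_model(function(chars, structure) mat, name = "matrix")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

onehot_model <- function(target) {
  n <- length(target)
  mat <- matrix(1e-12, n, 20, dimnames = list(NULL, AA_STANDARD))
  mat[cbind(seq_len(n), match(target, AA_STANDARD))] <- 1
  matrix_model(mat / rowSums(mat))
}

test_that("sampling follows the sharpened, constrained model distribution", {
  s <- pd_structure(ideal_helix(3))
  # a near-one-hot model decodes to its argmax for any seed
  target <- c("L", "E", "K")
  m <- onehot_model(target)
  for (seed in 1:10) {
    out <- sample_sequence(m, s, inv_temperature = 10, seed = seed)
    expect_equal(out$chars, target)
  }

  # two-outcome position at inverse temperature 10:
  # P(A) = .6^10 / (.6^10 + .4^10), computed independently
  s1 <- pd_structure(ideal_helix(1))
  mat <- matrix(0, 1, 20, dimnames = list(NULL, AA_STANDARD))
  mat[1, c("A", "L")] <- c(0.6, 0.4)
  m2 <- matrix_model(mat)
  draws <- vapply(1:10000, function(k)
    sample_sequence(m2, s1, inv_temperature = 10, seed = k)$chars, "")
  p_exp <- 0.6^10 / (0.6^10 + 0.4^10)
  p_obs <- mean(draws == "A")
  expect_lt(abs(p_obs - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 10000))

  # forbidden residues with nonzero model mass never appear
  cons <- redesign_constraints(forbidden = c("C", "A"))
  draws_f <- vapply(1:2000, function(k)
    sample_sequence(m2, s1, cons, inv_temperature = 1, seed = k)$chars, "")
  expect_false(any(draws_f == "A"))

  # fully forbidden position is an unsatisfiable constraint
  cons_bad <- redesign_constraints(forbidden = AA_STANDARD)
  expect_error(sample_sequence(m2, s1, cons_bad), class = "unsatisfiable_constraint")
})

test_that("empirical 3-position sample distribution matches the beta-adjusted product", {
  s <- pd_structure(ideal_helix(3))
  mat <- matrix(0, 3, 20, dimnames = list(NULL, AA_STANDARD))
  mat[1, c("A", "L")] <- c(0.55, 0.45)
  mat[2, c("E", "K")] <- c(0.5, 0.5)
  mat[3, c("G", "S")] <- c(0.48, 0.52)
  m <- matrix_model(mat)
  beta <- 10
  adj <- function(p) p^beta / sum(p^beta)
  p1 <- adj(c(0.55, 0.45)); p2 <- adj(c(0.5, 0.5)); p3 <- adj(c(0.48, 0.52))
  outcomes <- expand.grid(a = c("A", "L"), b = c("E", "K"), c = c("G", "S"),
                          stringsAsFactors = FALSE)
  probs <- apply(outcomes, 1, function(r)
    p1[match(r[1], c("A", "L"))] * p2[match(r[2], c("E", "K"))] *
      p3[match(r[3], c("G", "S"))])
  draws <- vapply(1:10000, function(k)
    sample_sequence(m, s, inv_temperature = beta, seed = k)$sequence, "")
  lev <- apply(outcomes, 1, paste, collapse = "")
  obs <- table(factor(draws, levels = lev))
  chi <- chisq.test(as.vector(obs), p = probs)
  expect_gt(chi$p.value, 0.01)
})

test_that("tied positions, frozen regions and the greedy limit behave exactly", {
  s <- pd_structure(ideal_helix(6))
  set.seed(1)
  mat <- matrix(runif(6 * 20), 6, 20, dimnames = list(NULL, AA_STANDARD))
  mat <- mat / rowSums(mat)
  m <- matrix_model(mat)

  cons <- redesign_constraints(tied_groups = list(c(1L, 4L), c(2L, 5L)))
  for (seed in 1:100) {
    ch <- sample_sequence(m, s, cons, seed = seed)$chars
    expect_identical(ch[1], ch[4])
    expect_identical(ch[2], ch[5])
  }

  frozen <- redesign_constraints(frozen = c(`3` = "W", `6` = "P"))
  for (seed in 1:25) {
    ch <- sample_sequence(m, s, frozen, seed = seed)$chars
    expect_identical(ch[c(3, 6)], c("W", "P"))
  }

  # beta -> infinity equals greedy argmax decoding (no forbidden residues)
  free <- redesign_constraints(forbidden = character(0))
  greedy <- AA_STANDARD[apply(mat, 1, which.max)]
  for (seed in 1:5) {
    out <- sample_sequence(m, s, free, inv_temperature = 1e6, seed = seed)
    expect_equal(out$chars, greedy)
  }
})

test_that("likelihood scoring matches closed forms and flags zero probability", {
  s <- pd_structure(ideal_helix(4))
  unif <- matrix(1 / 20, 4, 20, dimnames = list(NULL, AA_STANDARD))
  m <- matrix_model(unif)
  expect_equal(score_likelihood(m, "AAAA", s), -log(20), tolerance = 1e-12)

  target <- c("M", "K", "V", "L")
  mh <- onehot_model(target)
  expect_equal(score_likelihood(mh, "MKVL", s), 0, tolerance = 1e-9)

  zero <- matrix(0, 4, 20, dimnames = list(NULL, AA_STANDARD))
  zero[, "A"] <- 1
  ll <- score_likelihood(matrix_model(zero), "AKAA", s)
  expect_identical(ll, structure(-Inf, zero_probability = TRUE))
})

test_that("redesign batches are deduplicated, frozen-respecting and rank-ordered", {
  s <- pd_structure(ideal_helix(8))
  set.seed(4)
  mat <- matrix(rgamma(8 * 20, 0.5), 8, 20, dimnames = list(NULL, AA_STANDARD))
  mat <- mat / rowSums(mat)
  m <- matrix_model(mat)
  cons <- redesign_constraints(frozen = c(`1` = "M"))
  batch <- redesign_batch(m, s, cons, n_samples = 100L, seed = 9L)
  expect_false(any(duplicated(batch$sequence)))
  expect_true(all(substr(batch$sequence, 1, 1) == "M"))
  expect_true(all(diff(batch$loglik) <= 1e-12))
  expect_equal(batch$rank, seq_len(nrow(batch)))
  expect_equal(sum(batch$n_drawn), 100L)

  # sharply peaked model: the top-ranked sample is the argmax sequence
  peaked <- onehot_model(c("L", "E", "K", "L", "A", "A", "E", "K"))
  top <- replicate(20, {
    redesign_batch(peaked, s, n_samples = 5L,
                   seed = sample.int(1e6, 1))$sequence[1]
  })
  expect_true(mean(top == "LEKLAAEK") >= 0.95)
})

test_that("the reference profile model is a valid, rigid-invariant sequence model", {
  s <- random_structure(30, seed = 17)
  m <- reference_profile_model(s)
  pr <- m$probs(rep(AA_MASK, 30), s)
  expect_equal(unname(rowSums(pr)), rep(1, 30), tolerance = 1e-9)
  expect_true(all(pr > 0))

  moved <- transform_structure(s, random_rotation(2), c(7, -1, 3))
  pr2 <- reference_profile_model(moved)$probs(rep(AA_MASK, 30), moved)
  expect_equal(pr, pr2, tolerance = 1e-9)

  # a densely buried position leans hydrophobic; an exposed one polar
  clump <- pd_structure(rbind(matrix(rnorm(60, sd = 3), 20, 3),
                              c(60, 0, 0)))
  prc <- reference_profile_model(clump)$probs(rep(AA_MASK, 21), clump)
  hydro <- c("A", "L", "I", "V", "F", "M", "W")
  polar <- c("E", "K", "R", "D", "Q", "N", "S", "T", "H")
  buried_idx <- which.max(rowSums(as.matrix(dist(atom_coords(clump, "CA"))) < 10))
  expect_gt(sum(prc[buried_idx, hydro]), sum(prc[buried_idx, polar]))
  expect_gt(sum(prc[21, polar]), sum(prc[21, hydro]))
})
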