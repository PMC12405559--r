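test_that("plate preprocessing removes edge bias and flags pinning misses", {
  # constructed plate: interior median 100, edge median 125
  lay <- tic_layout()
  p <- data.frame(plate = "p1", lay, opacity = ifelse(lay$edge, 125, 100))
  p$opacity[which(lay$edge)[1]] <- 150
  p$opacity[which(!lay$edge)[1]] <- 0      # pinning miss
  out <- preprocess_plate(p)
  expect_equal(out$opacity[which(lay$edge)[1]], 150 * 100 / 125, tolerance = 1e-9)
  expect_true(out$missing[which(!lay$edge)[1]])

  # no edge bias: values unchanged
  flat <- data.frame(plate = "p2", lay, opacity = 100)
  expect_equal(preprocess_plate(flat)$opacity, flat$opacity)

  empty <- data.frame(plate = "p3", lay, opacity = 0)
  expect_error(preprocess_plate(empty), class = "empty_plate")
})

test_that("normalisation divides by GFP controls and averages technical replicates", {
  lay <- tic_layout()
  p <- data.frame(plate = "both_bio1", condition = "both", bio_rep = 1L,
                  lay, opacity = 1000)
  gfp <- grepl("^GFP", p$strain)
  p$opacity[!gfp] <- 1200
  fit <- normalize_fitness(p)
  # GFP mean 1000 -> blocker fitness 1.2; controls normalise to 1
  expect_equal(unique(fit$fitness[!grepl("^GFP", fit$strain)]), 1.2)
  expect_equal(mean(fit$fitness[grepl("^GFP", fit$strain)]), 1.0)

  # technical replicates 1.2 and 1.4 average to 1.3
  i <- which(p$strain == "blocker_01" & p$donor_rep == 1)
  p$opacity[i] <- c(1200, 1400)
  fit2 <- normalize_fitness(p)
  expect_equal(fit2$fitness[fit2$strain == "blocker_01" & fit2$donor_rep == 1],
               1.3, tolerance = 1e-9)
})

test_that("effects are fitness ratios with the GFP null sized as designed", {
  scr <- simulate_screen(effects = c(blocker_01 = 3), sigma = 0.05, seed = 2)
  fit <- normalize_fitness(scr)
  eff <- blocker_effect(fit)
  expect_equal(length(eff$gfp), 16L)                       # null sample size
  b1 <- eff$blockers[eff$blockers$strain == "blocker_01", ]
  expect_equal(nrow(b1), 6L)                               # 2 donor x 3 recipient
  expect_equal(mean(b1$effect), 3, tolerance = 0.15)
  null_mean <- mean(eff$blockers$effect[eff$blockers$strain != "blocker_01"])
  expect_equal(null_mean, 1, tolerance = 0.05)
})

test_that("Welch test matches the textbook formula and handles degenerate ties", {
  set.seed(21)
  for (k in 1:1000) {
    x <- rnorm(6, mean = runif(1, 0.5, 3), sd = runif(1, 0.05, 0.5))
    y <- rnorm(16, mean = 1, sd = runif(1, 0.05, 0.5))
    ref <- welch_naive(x, y)
    tt <- t.test(x, y, var.equal = FALSE)
    expect_equal(tt$p.value, ref$p, tolerance = 1e-10)
    expect_equal(unname(tt$parameter), ref$df, tolerance = 1e-8)
  }

  # identical constant samples: p = 1, no hit
  scr <- simulate_screen(sigma = 0.05, seed = 3)
  fit <- normalize_fitness(scr)
  eff <- blocker_effect(fit)
  eff$blockers$effect <- 1
  eff$gfp <- rep(1, 16)
  res <- test_blockers(eff)
  expect_true(all(res$t_p == 1))
  expect_false(any(res$hit))
})

test_that("planted strong blockers are called; sub-cutoff effects are not hits", {
  scr <- simulate_screen(effects = c(blocker_05 = 2), sigma = 0.08, seed = 4)
  res <- tic_analyze(scr)
  r5 <- res[res$strain == "blocker_05", ]
  expect_true(r5$hit)
  expect_equal(r5$effect_size, 2, tolerance = 0.25)

  # significant but small effect fails the effect-size cutoff
  eff <- list(blockers = data.frame(strain = "b", donor_rep = 1,
                                    bio_rep = 1:6,
                                    effect = 1.05 + rnorm(6, sd = 1e-4)),
              gfp = 1 + rnorm(16, sd = 1e-4))
  res2 <- test_blockers(eff, effect_cutoff = 1.1)
  expect_lt(res2$t_p, 1e-6)
  expect_false(res2$hit)

  # leaky and toxic flags from the single-induction conditions
  scr2 <- simulate_screen(effects = c(blocker_02 = 2),
                          leaky = "blocker_02", toxic = "blocker_03",
                          sigma = 0.05, seed = 6)
  res3 <- tic_analyze(scr2)
  expect_true(res3$leaky[res3$strain == "blocker_02"])
  expect_true(res3$toxic[res3$strain == "blocker_03"])
  expect_false(any(res3$toxic[res3$strain == "blocker_01"]))
})

test_that("the analysis is invariant to rescaling whole plates", {
  scr <- simulate_screen(effects = c(blocker_07 = 1.6), sigma = 0.1, seed = 9)
  res1 <- tic_analyze(scr)
  scaled <- scr
  for (pl in unique(scr$plate)) {
    f <- runif(1, 0.5, 5)
    scaled$opacity[scaled$plate == pl] <- scaled$opacity[scaled$plate == pl] * f
  }
  res2 <- tic_analyze(scaled)
  expect_equal(res1$effect_size, res2$effect_size, tolerance = 1e-9)
  expect_equal(res1$t_p, res2$t_p, tolerance = 1e-9)
})

test_that("simulated screens carry their layout and ground truth", {
  lay <- tic_layout()
  expect_equal(nrow(lay), 384L)
  expect_equal(sum(grepl("^GFP", lay$strain)), 32L)
  scr <- simulate_screen(seed = 1)
  expect_equal(nrow(scr), 384L * 4L * 3L)
  expect_setequal(unique(scr$condition), c("none", "arabinose", "iptg", "both"))
  expect_named(attr(scr, "truth"), c("effects", "leaky", "toxic"))

  # edge inflation is removed by preprocessing (medians re-agree within 1%)
  pre <- preprocess_plate(scr[scr$plate == "none_bio1", ])
  ratio <- median(pre$opacity[pre$edge & !pre$missing]) /
    median(pre$opacity[!pre$edge & !pre$missing])
  expect_lt(abs(ratio - 1), 0.01)
})
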