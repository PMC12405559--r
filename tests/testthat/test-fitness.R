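test_that("confidence terms reproduce their analytic extremes and arithmetic", {
  perfect <- make_prediction(n = 12, plddt = 100, pae = 0, ptm = 1)
  ct <- confidence_terms(perfect)
  expect_equal(unlist(ct), c(l_pae = 1, l_plddt = 1, l_conf = 1))

  zero <- make_prediction(n = 12, plddt = 0, pae = 31.75, ptm = 0)
  # diagonal is 0 by construction; force the full worst case explicitly
  zero$pae[] <- 31.75
  ct0 <- confidence_terms(zero)
  expect_equal(unlist(ct0), c(l_pae = 0, l_plddt = 0, l_conf = 0))

  # mean pAE = pae_max/2 and pLDDT = 80 -> l_conf = (0.5 + 0.8)/2
  half <- make_prediction(n = 12, plddt = 80, pae = 31.75 / 2, ptm = 0.5)
  half$pae[] <- 31.75 / 2
  expect_equal(confidence_terms(half)$l_conf, 0.65, tolerance = 1e-12)
})

test_that("interface term averages both off-diagonal blocks exactly", {
  p <- make_prediction(n = 10, chains = 2L, pae = 5)
  # asymmetric interface blocks
  p$pae[1:5, 6:10] <- 2
  p$pae[6:10, 1:5] <- 8
  manual <- 0
  cnt <- 0
  for (i in 1:5) for (j in 6:10) {
    manual <- manual + p$pae[i, j] + p$pae[j, i]; cnt <- cnt + 2
  }
  expect_equal(ipae_term(p, 1:5, 6:10), 1 - (manual / cnt) / p$pae_max,
               tolerance = 1e-12)
  expect_equal(ipae_term(p, "A", "B"), ipae_term(p, 1:5, 6:10))

  blk0 <- p; blk0$pae[1:5, 6:10] <- 0; blk0$pae[6:10, 1:5] <- 0
  expect_equal(ipae_term(blk0, 1:5, 6:10), 1)
  blkm <- p; blkm$pae[1:5, 6:10] <- p$pae_max; blkm$pae[6:10, 1:5] <- p$pae_max
  expect_equal(ipae_term(blkm, 1:5, 6:10), 0)

  expect_error(ipae_term(p, 1:5, 4:10), class = "partition_error")
})

test_that("approximate TM term: identity extreme, transfer function, d0 plumbing", {
  s <- random_structure(50, seed = 2)
  p1 <- pd_prediction(s, rep(90, 50), matrix(0, 50, 50), 0.9)
  moved <- transform_structure(s, random_rotation(6), c(2, 2, 2))
  p2 <- pd_prediction(moved, rep(90, 50), matrix(0, 50, 50), 0.9)
  # local frames co-transform: rigid motion leaves aligned error at zero
  expect_equal(approx_tm_term(p1, p2), 1.0, tolerance = 1e-9)

  d0_50 <- tm_d0(50)
  expect_equal(d0_50, 2.2561, tolerance = 1e-4)
  expect_equal(tm_transfer(d0_50, d0_50), 0.5)
  expect_equal(tm_transfer(0, d0_50), 1)
  expect_equal(tm_transfer(d0_50, d0_50, squared = TRUE), 0.5)

  p3 <- pd_prediction(random_structure(49, seed = 3), rep(90, 49),
                      matrix(0, 49, 49), 0.9)
  expect_error(approx_tm_term(p1, p3), class = "structural_mismatch")
})

test_that("site-distance and radius penalties follow their threshold arithmetic", {
  # binder chain A at a controlled distance from 'site' residue on chain B
  mk <- function(gap) {
    co <- array(0, c(2, 4, 3), dimnames = list(NULL, c("N", "CA", "C", "O"), NULL))
    co[2, , 1] <- gap
    pd_prediction(pd_structure(co, chain_lengths = c(1, 1)),
                  rep(90, 2), matrix(0, 2, 2), 0.9)
  }
  expect_equal(site_distance_penalty(mk(3), 1, 2, r = 6), 0)
  expect_equal(site_distance_penalty(mk(10), 1, 2, r = 6), 4)

  # penalty equals brute-force min over all residue pairs
  p <- make_prediction(n = 20, chains = 2L, seed = 31)
  ca <- atom_coords(p$structure, "CA")
  bi <- 1:10; si <- 15:18
  brute <- min(as.matrix(dist(ca))[bi, si])
  expect_equal(site_distance_penalty(p, bi, si, r = 6),
               max(6, brute) - 6, tolerance = 1e-9)

  compact <- make_prediction(n = 30, seed = 7)
  rg <- radius_of_gyration(compact$structure)
  expect_equal(radius_penalty(compact, R = rg + 1), 0)
  expect_equal(radius_penalty(compact, R = rg / 2), (rg - rg / 2) / (rg / 2),
               tolerance = 1e-9)
  expect_error(radius_penalty(compact, R = -1), class = "invalid_spec")

  # an elongated chain is penalised at least as much as a compact one
  stretched <- pd_prediction(pd_structure(cbind(3.8 * (0:29), 0, 0)),
                             rep(90, 30), matrix(0, 30, 30), 0.9)
  R <- default_rg_threshold(30)
  expect_gte(radius_penalty(stretched, R = R), radius_penalty(compact, R = R))
})

test_that("composite fitness matches hand-computed values for each task", {
  # perfect confidences, compact structure, N = 2 chains -> exactly 2
  s <- pd_structure(rbind(ideal_helix(10), ideal_helix(10) + 5),
                    chain_lengths = c(10, 10))
  perfect <- pd_prediction(s, rep(100, 20), matrix(0, 20, 20), 1)
  spec <- fitness_spec("denovo", R = 100)
  expect_equal(composite_fitness(spec, list(complex = perfect)), 2.0,
               tolerance = 1e-12)

  # binder: l_ipAE = 0.8, l_conf(X) = 0.6, close to site, compact
  n <- 10
  co <- array(0, c(n, 4, 3), dimnames = list(NULL, c("N", "CA", "C", "O"), NULL))
  co[, , 1] <- matrix(seq(0, 3, length.out = n), n, 4)  # everything within 6 A
  pae <- matrix(0, n, n)
  xi <- 1:5; ti <- 6:10
  pae[xi, ti] <- 0.2 * 31.75; pae[ti, xi] <- 0.2 * 31.75   # l_ipAE = 0.8
  pae[xi, xi] <- 0.4 * 31.75                               # l_pae(X) = 0.6
  diag(pae) <- 0
  # l_pae(X) uses the diagonal too; set pLDDT so l_conf(X) is exactly 0.6
  pX <- pae[xi, xi]
  l_pae_x <- 1 - mean(pX) / 31.75
  plddt_x <- (2 * 0.6 - l_pae_x) * 100
  pred <- pd_prediction(pd_structure(co, chain_lengths = c(5, 5)),
                        c(rep(plddt_x, 5), rep(90, 5)), pae, 0.9)
  spec_b <- fitness_spec("binder", site = 1, R = 100,
                         designed = "A", target = "B")
  expect_equal(composite_fitness(spec_b, list(complex = pred)),
               0.7 * 0.8 + 0.3 * 0.6, tolerance = 1e-9)

  # change task: no conformational change -> L_TM = 1, ReLU penalty active
  mono_s <- random_structure(8, seed = 12)
  mono <- pd_prediction(mono_s, rep(100, 8), matrix(0, 8, 8), 1)
  cx_s <- pd_structure(rbind(atom_coords(mono_s, "CA"),
                             atom_coords(mono_s, "CA") + 20),
                       chain_lengths = c(8, 8))
  cx_co <- cx_s$coords
  cx_co[1:8, , ] <- mono_s$coords   # chain X identical in the complex
  cx <- pd_prediction(pd_structure(cx_co, chain_lengths = c(8, 8)),
                      rep(100, 16), matrix(0, 16, 16), 1)
  spec_c <- fitness_spec("change", alpha = 0.6, tm_max = 0.5, designed = "A")
  got <- composite_fitness(spec_c, list(monomer = mono, complex = cx))
  expect_equal(got, 0.6 * 1 + 0.4 * 1 - (1 - 0.5), tolerance = 1e-9)

  # dead zone: TM below the ceiling contributes exactly zero penalty
  spec_c2 <- fitness_spec("change", alpha = 0.6, tm_max = 1.0, designed = "A")
  expect_equal(composite_fitness(spec_c2, list(monomer = mono, complex = cx)),
               1.0, tolerance = 1e-9)

  expect_error(composite_fitness(spec_c, list(complex = cx)),
               class = "incomplete_task")
})

test_that("composite fitness is monotone in confidences and penalties", {
  base <- make_prediction(n = 16, plddt = 80, pae = 6, ptm = 0.7)
  spec <- fitness_spec("denovo", R = 100)
  f0 <- composite_fitness(spec, list(complex = base))
  better <- base; better$plddt <- base$plddt + 5
  expect_gt(composite_fitness(spec, list(complex = better)), f0)
  worse <- base; worse$pae <- base$pae * 1.5
  expect_lt(composite_fitness(spec, list(complex = worse)), f0)
  # tighter radius threshold can only reduce fitness
  spec_tight <- fitness_spec("denovo", R = 1)
  expect_lte(composite_fitness(spec_tight, list(complex = base)), f0)
})
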