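# Independent reference implementations ("oracles") used to cross-check
# the package. These deliberately use different mechanisms than the
# implementation under test.

# Random compact-ish CA walk as a test structure.
random_structure <- function(n, seed, chains = 1L) {
  set.seed(seed)
  per <- rep(n %/% chains, chains)
  per[1] <- per[1] + n %% chains
  ca <- NULL
  for (c in seq_len(chains)) {
    steps <- matrix(rnorm(per[c] * 3), ncol = 3)
    steps <- 3.8 * steps / sqrt(rowSums(steps^2))
    x <- apply(steps, 2, cumsum)
    x[, 1] <- x[, 1] + (c - 1) * 15
    ca <- rbind(ca, x)
  }
  pd_structure(ca, chain_lengths = per)
}

random_rotation <- function(seed) {
  set.seed(seed)
  m <- matrix(rnorm(9), 3, 3)
  qr_r <- qr(m)
  q <- qr.Q(qr_r)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

euler_rot <- function(a, b, c) {
  rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1),
                           3, 3, byrow = TRUE)
  ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)),
                           3, 3, byrow = TRUE)
  rz(a) %*% ry(b) %*% rz(c)
}

# Brute-force minimal RMSD: coarse Euler-angle grid followed by
# Nelder-Mead refinement; no SVD anywhere.
rmsd_gridsearch <- function(p, q) {
  pc <- sweep(p, 2, colMeans(p))
  qc <- sweep(q, 2, colMeans(q))
  obj <- function(ang) {
    r <- euler_rot(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((pc %*% t(r) - qc)^2)))
  }
  best <- Inf; best_ang <- c(0, 0, 0)
  grid <- seq(0, 2 * pi, length.out = 13)[-13]
  gridb <- seq(0, pi, length.out = 7)
  for (a in grid) for (b in gridb) for (cc in grid) {
    v <- obj(c(a, b, cc))
    if (v < best) { best <- v; best_ang <- c(a, b, cc) }
  }
  opt <- optim(best_ang, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  min(best, opt$value)
}

# Scalar-loop contact counter.
contacts_naive <- function(s, partition, threshold = 4.0) {
  n <- n_residues(s)
  chain_of <- rep(seq_along(s$chain_lengths), s$chain_lengths)
  atoms_of <- function(i) {
    m <- matrix(s$coords[i, , ], ncol = 3)
    if (!is.null(s$sidechains) && !is.null(s$sidechains[[i]]))
      m <- rbind(m, s$sidechains[[i]])
    m
  }
  cnt <- 0L
  for (i in seq_len(max(n - 1, 0))) for (j in seq(i + 1, n)) {
    same <- chain_of[i] == chain_of[j]
    if (partition == "intra" && (!same || j - i <= 1)) next
    if (partition == "interface" && same) next
    ai <- atoms_of(i); aj <- atoms_of(j)
    found <- FALSE
    for (u in seq_len(nrow(ai))) {
      for (v in seq_len(nrow(aj))) {
        if (sqrt(sum((ai[u, ] - aj[v, ])^2)) < threshold) { found <- TRUE; break }
      }
      if (found) break
    }
    if (found) cnt <- cnt + 1L
  }
  cnt
}

# Textbook Welch t-test.
welch_naive <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Naive success-threshold logic, written independently.
classify_naive <- function(plddt, scrmsd, ipae = NA) {
  lax <- isTRUE(plddt > 70) && isTRUE(scrmsd < 2)
  strict <- if (is.na(ipae)) NA else
    isTRUE(plddt > 80) && isTRUE(scrmsd < 1) && isTRUE(ipae < 10)
  list(lax = lax, strict = strict)
}

# Naive filter-cascade logic.
cascade_naive <- function(ll, plddt01, ptm, sol = NULL) {
  if (ll < -0.1) return(FALSE)
  if (plddt01 * ptm < 0.5) return(FALSE)
  if (!is.null(sol) && sol < 1) return(FALSE)
  TRUE
}

# A constant prediction fixture with prescribed confidence values.
make_prediction <- function(n = 20, plddt = 90, pae = 2, ptm = 0.8,
                            chains = 1L, pae_max = 31.75, seed = 1) {
  s <- random_structure(n, seed, chains)
  pm <- matrix(pae, n, n); diag(pm) <- 0
  pd_prediction(s, rep(plddt, length.out = n), pm, ptm, pae_max = pae_max)
}

# Toy additive-plus-one-coupling fitness landscape on a small alphabet;
# the optimum is recovered by exhaustive enumeration.
toy_landscape <- function(len = 8, alphabet = c("A", "E", "K", "L"), seed = 42) {
  set.seed(seed)
  w <- matrix(runif(len * length(alphabet)), len, length(alphabet),
              dimnames = list(NULL, alphabet))
  score_seq <- function(seqs) {
    vapply(seqs, function(s) {
      ch <- strsplit(s, "")[[1]]
      idx <- match(ch, alphabet)
      sum(w[cbind(seq_len(len), idx)]) + 0.5 * (idx[1] == idx[len])
    }, 1)
  }
  # exhaustive enumeration of the full landscape
  grid <- do.call(expand.grid, rep(list(seq_along(alphabet)), len))
  base <- matrix(0, nrow(grid), 1)
  tot <- rep(0, nrow(grid))
  for (p in seq_len(len)) tot <- tot + w[p, grid[[p]]]
  tot <- tot + 0.5 * (grid[[1]] == grid[[len]])
  list(alphabet = alphabet, len = len, score = score_seq,
       optimum = max(tot))
}
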