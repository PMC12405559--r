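#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation (determinant +1; no reflection, since
#' chirality is physical) and translation minimising the RMSD between
#' two point sets, via SVD of the cross-covariance matrix.
#'
#' @param p,q Numeric `n x 3` matrices (p is rotated onto q).
#' @param weights Optional non-negative per-point weights.
#' @return List with `rotation` (3x3), `translation` (length 3) such that
#'   `p %*% t(rotation) + translation` superposes p onto q, and `rmsd`.
#' @export
kabsch_superpose <- function(p, q, weights = NULL) {
  stopifnot(is.matrix(p), is.matrix(q), ncol(p) == 3L, ncol(q) == 3L)
  if (nrow(p) != nrow(q))
    pd_stop("structural_mismatch", "point sets differ in size")
  if (nrow(p) < 2L)
    pd_stop("degenerate_input", "need >= 2 points for superposition")
  if (is.null(weights)) weights <- rep(1, nrow(p))
  w <- weights / sum(weights)
  cp <- colSums(p * w)
  cq <- colSums(q * w)
  pc <- sweep(p, 2, cp)
  qc <- sweep(q, 2, cq)
  h <- t(pc * w) %*% qc
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  aligned <- pc %*% t(rot)
  rmsd <- sqrt(sum(weights * rowSums((aligned - qc)^2)) / sum(weights))
  list(rotation = rot, translation = as.numeric(cq - cp %*% t(rot)), rmsd = rmsd)
}

resolve_atom_sets <- function(a, b, atoms, residues = NULL) {
  stopifnot(inherits(a, "pd_structure"), inherits(b, "pd_structure"))
  if (n_residues(a) != n_residues(b))
    pd_stop("structural_mismatch", "structures differ in residue count")
  list(pa = atom_coords(a, atoms, residues), pb = atom_coords(b, atoms, residues))
}

#' Minimal RMSD under rigid superposition
#'
#' Root-mean-square deviation between two structures after optimal
#' proper rigid superposition of the selected atoms (residue
#' correspondence is the identity mapping). This is the scRMSD metric
#' when comparing a design's generated structure with the re-predicted
#' structure of its sequence; CA atoms are the conventional selection.
#'
#' @param a,b [pd_structure()] objects with equal residue counts.
#' @param atoms Atom selection (see [atom_coords()]); default `"CA"`.
#' @return RMSD in Angstrom. Symmetric in its arguments.
#' @export
kabsch_rmsd <- function(a, b, atoms = "CA") {
  xs <- resolve_atom_sets(a, b, atoms)
  kabsch_superpose(xs$pa, xs$pb)$rmsd
}

#' TM-score d0 normalisation length
#'
#' `d0(L) = 1.24 (max(L, 19) - 15)^(1/3) - 1.8`, clamped to at least
#' 0.5 Angstrom so very short chains keep a positive scale.
#'
#' @param l Residue count.
#' @return d0 in Angstrom.
#' @export
tm_d0 <- function(l) {
  max(1.24 * (max(l, 19) - 15)^(1 / 3) - 1.8, 0.5)
}

#' TM-score between two equal-length structures
#'
#' Template-modelling score over the identity residue mapping with the
#' standard d0 normalisation (see [tm_d0()]); the superposition is
#' chosen to maximise the score by iterating weighted Kabsch fits with
#' the TM weights `1/(1 + (d_i/d0)^2)`, keeping the best score seen.
#' No structural alignment search is performed.
#'
#' @param a,b [pd_structure()] objects with equal residue counts.
#' @param max_iter Iteration cap for the superposition refinement.
#' @return Score in (0, 1]; 1 for congruent structures.
#' @export
tm_score <- function(a, b, max_iter = 30L) {
  xs <- resolve_atom_sets(a, b, "CA")
  pa <- xs$pa; pb <- xs$pb
  l <- nrow(pa)
  d0 <- tm_d0(l)
  score_of <- function(fit) {
    d2 <- rowSums((sweep(pa %*% t(fit$rotation), 2, fit$translation, "+") - pb)^2)
    mean(1 / (1 + d2 / d0^2))
  }
  fit <- kabsch_superpose(pa, pb)
  best <- score_of(fit)
  w <- rep(1, l)
  for (it in seq_len(max_iter)) {
    d2 <- rowSums((sweep(pa %*% t(fit$rotation), 2, fit$translation, "+") - pb)^2)
    w_new <- 1 / (1 + d2 / d0^2)
    if (max(abs(w_new - w)) < 1e-10) break
    w <- w_new
    fit <- kabsch_superpose(pa, pb, weights = w)
    s <- score_of(fit)
    if (s > best) best <- s
  }
  best
}

#' Radius of gyration
#'
#' Root-mean-square distance of the selected atoms from their centroid,
#' the standard compactness measure for a fold.
#'
#' @param s A [pd_structure()].
#' @param atoms Atom selection; default `"CA"`.
#' @param residues Optional residue subset.
#' @return Radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(s, atoms = "CA", residues = NULL) {
  xyz <- atom_coords(s, atoms, residues)
  if (nrow(xyz) < 1L) pd_stop("degenerate_input", "empty atom selection")
  ctr <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2, ctr)^2)))
}

#' Residue-pair contact count
#'
#' Counts residue pairs with any heavy-atom pair within the distance
#' threshold. `partition = "intra"` counts within-chain pairs excluding
#' sequence-adjacent neighbours; `partition = "interface"` counts
#' cross-chain pairs only. Side-chain atoms are included when present.
#'
#' @param s A [pd_structure()].
#' @param partition `"intra"` or `"interface"`.
#' @param threshold Heavy-atom distance threshold in Angstrom (default 4).
#' @return Integer contact count (0 for structures with no eligible pairs).
#' @export
contact_count <- function(s, partition = c("intra", "interface"), threshold = 4.0) {
  partition <- match.arg(partition)
  n <- n_residues(s)
  chain_of <- rep(seq_along(s$chain_lengths), s$chain_lengths)
  heavy <- lapply(seq_len(n), function(i) residue_heavy_atoms(s, i))
  count <- 0L
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      same <- chain_of[i] == chain_of[j]
      if (partition == "intra" && (!same || j - i <= 1L)) next
      if (partition == "interface" && same) next
      if (min_pair_dist(heavy[[i]], heavy[[j]]) < threshold) count <- count + 1L
    }
  }
  count
}

min_pair_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * (a %*% t(b))
  sqrt(max(min(d2), 0))
}

#' Per-residue root-mean-square fluctuation
#'
#' RMSF of the selected atoms about the ensemble-average structure.
#' Each snapshot is rigidly superposed (backbone Kabsch) onto the
#' running ensemble mean; the mean and the alignment are refined over
#' two passes, which is stable and removes any global rigid motion.
#'
#' @param e A [pd_ensemble()] with at least two snapshots.
#' @param atoms Atom selection used for the per-residue RMSF (default
#'   `"CA"`); alignment always uses the full backbone.
#' @param align Superpose each snapshot onto the ensemble mean before
#'   measuring fluctuations (default). Set `FALSE` for pre-aligned
#'   trajectories.
#' @param passes Mean-refinement passes (default 2).
#' @return Numeric vector, one RMSF value (Angstrom) per residue.
#' @export
rmsf <- function(e, atoms = "CA", align = TRUE, passes = 2L) {
  stopifnot(inherits(e, "pd_ensemble"))
  if (length(e) < 2L) pd_stop("degenerate_input", "need >= 2 snapshots for RMSF")
  coords <- lapply(e$structures, atom_coords, atoms = "backbone")
  ref <- coords[[1]]
  aligned <- coords
  if (align) {
    for (p in seq_len(passes)) {
      aligned <- lapply(coords, function(m) {
        fit <- kabsch_superpose(m, ref)
        sweep(m %*% t(fit$rotation), 2, fit$translation, "+")
      })
      ref <- Reduce(`+`, aligned) / length(aligned)
    }
  } else {
    ref <- Reduce(`+`, aligned) / length(aligned)
  }
  n <- n_residues(e$structures[[1]])
  sel_atoms <- if (identical(atoms, "backbone")) BB_ATOMS else atoms
  atom_rows <- function(i) (i - 1L) * 4L + match(sel_atoms, BB_ATOMS)
  vapply(seq_len(n), function(i) {
    rows <- atom_rows(i)
    dev2 <- vapply(aligned, function(m) mean(rowSums((m[rows, , drop = FALSE] -
                                                        ref[rows, , drop = FALSE])^2)), 1)
    sqrt(mean(dev2))
  }, 1)
}
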