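#' Structure-prediction result
#'
#' A `pd_prediction` bundles the outputs every fitness term consumes: a
#' predicted [pd_structure()], the per-residue pLDDT confidence (0-100),
#' the pairwise predicted aligned error matrix pAE (Angstrom, bounded by
#' `pae_max`) and the global pTM score in \[0, 1\]. Invariants are checked
#' at construction: the pAE matrix is square with side equal to the
#' residue count, pLDDT covers every residue, and all values lie within
#' their stated ranges.
#'
#' @param structure A [pd_structure()].
#' @param plddt Numeric vector in \[0, 100\], one value per residue.
#' @param pae Square numeric matrix in \[0, pae_max\].
#' @param ptm Scalar in \[0, 1\].
#' @param pae_max Upper bound of the predictor's pAE range (Angstrom;
#'   default 31.75, the usual error-bin ceiling).
#' @return Object of class `pd_prediction`.
#' @export
pd_prediction <- function(structure, plddt, pae, ptm, pae_max = 31.75) {
  stopifnot(inherits(structure, "pd_structure"))
  n <- n_residues(structure)
  if (length(plddt) != n)
    pd_stop("structural_mismatch", "pLDDT length must equal residue count")
  if (!is.matrix(pae) || any(dim(pae) != n))
    pd_stop("structural_mismatch", "pAE must be an n x n matrix")
  if (any(plddt < 0 | plddt > 100))
    pd_stop("range_error", "pLDDT outside [0, 100]")
  if (any(pae < 0) || any(pae > pae_max + 1e-9))
    pd_stop("range_error", "pAE outside [0, pae_max]")
  if (ptm < 0 || ptm > 1) pd_stop("range_error", "pTM outside [0, 1]")
  structure(list(structure = structure, plddt = as.numeric(plddt), pae = pae,
                 ptm = as.numeric(ptm), pae_max = pae_max),
            class = "pd_prediction")
}

#' @export
print.pd_prediction <- function(x, ...) {
  cat(sprintf("<pd_prediction> %d residues | mean pLDDT %.1f | mean pAE %.2f A | pTM %.3f\n",
              n_residues(x$structure), mean(x$plddt), mean(x$pae), x$ptm))
  invisible(x)
}

#' Validate prediction invariants
#'
#' Re-checks the `pd_prediction` invariants on an existing object;
#' useful against predictions produced by third-party oracle plugins.
#'
#' @param p A `pd_prediction`.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
validate_prediction <- function(p) {
  stopifnot(inherits(p, "pd_prediction"))
  pd_prediction(p$structure, p$plddt, p$pae, p$ptm, p$pae_max)
  invisible(TRUE)
}

# Local backbone frame at residue j: orthonormal basis from N, CA, C
# (Gram-Schmidt on CA->C and CA->N). Returns list(origin, basis 3x3).
residue_frame <- function(s, j) {
  nca <- s$coords[j, "N", ] - s$coords[j, "CA", ]
  cca <- s$coords[j, "C", ] - s$coords[j, "CA", ]
  e1 <- cca / sqrt(sum(cca^2))
  u2 <- nca - sum(nca * e1) * e1
  e2 <- u2 / sqrt(sum(u2^2))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  list(origin = s$coords[j, "CA", ], basis = cbind(e1, e2, e3))
}

#' Aligned-error matrix between two conformations of the same chain
#'
#' `AE[i, j]` is the positional error of residue i's CA when the two
#' structures are superposed on the local backbone frame of residue j --
#' the aligned-error construction used for predicted aligned error,
#' generalised to a pair of observed structures.
#'
#' @param a,b [pd_structure()] objects with equal residue counts.
#' @param residues Optional residue subset (frame and target residues).
#' @return Numeric matrix of aligned errors (Angstrom).
#' @export
aligned_error <- function(a, b, residues = NULL) {
  if (n_residues(a) != n_residues(b))
    pd_stop("structural_mismatch", "structures differ in residue count")
  if (is.null(residues)) residues <- seq_len(n_residues(a))
  ca_a <- atom_coords(a, "CA", residues)
  ca_b <- atom_coords(b, "CA", residues)
  m <- length(residues)
  ae <- matrix(0, m, m)
  for (jj in seq_len(m)) {
    fa <- residue_frame(a, residues[jj])
    fb <- residue_frame(b, residues[jj])
    la <- sweep(ca_a, 2, fa$origin) %*% fa$basis
    lb <- sweep(ca_b, 2, fb$origin) %*% fb$basis
    ae[, jj] <- sqrt(rowSums((la - lb)^2))
  }
  ae
}

#' pTM computed from a pAE matrix
#'
#' The usual reduction of a pairwise error matrix to a single predicted
#' TM score: `max_j mean_i 1 / (1 + (pae[i,j]/d0)^2)` with the standard
#' d0 normalisation for the residue count.
#'
#' @param pae Square pAE matrix (Angstrom).
#' @return Scalar in (0, 1].
#' @export
ptm_from_pae <- function(pae) {
  stopifnot(is.matrix(pae), nrow(pae) == ncol(pae))
  d0 <- tm_d0(nrow(pae))
  max(colMeans(1 / (1 + (pae / d0)^2)))
}
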