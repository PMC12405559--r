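#' Protein backbone structure
#'
#' A `pd_structure` stores per-residue backbone coordinates (N, CA, C, O;
#' Angstrom) as an `n x 4 x 3` array, a chain map aligned with a
#' [chained_seq()], and optional per-residue side-chain heavy-atom
#' coordinates. Coordinates must be finite and the coordinate array must
#' cover every residue of the chain map.
#'
#' @param coords Numeric array `n x 4 x 3`; the second dimension must be
#'   named `c("N","CA","C","O")`. Alternatively an `n x 3` matrix of CA
#'   coordinates, in which case the remaining backbone atoms are placed
#'   in idealised positions along the local chain direction.
#' @param chain_lengths Integer vector of residues per chain (default:
#'   single chain covering everything).
#' @param chain_ids Chain labels.
#' @param sidechains Optional list of length `n`; each element `NULL` or a
#'   matrix of heavy-atom coordinates (columns x, y, z).
#' @return An object of class `pd_structure`.
#' @export
pd_structure <- function(coords, chain_lengths = NULL, chain_ids = NULL,
                         sidechains = NULL) {
  if (is.matrix(coords) && ncol(coords) == 3L) {
    if (!all(is.finite(coords)))
      pd_stop("degenerate_input", "non-finite coordinates")
    coords <- backbone_from_ca(coords)
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3L,
            dim(coords)[2] == 4L, dim(coords)[3] == 3L)
  if (is.null(dimnames(coords)[[2]])) dimnames(coords)[[2]] <- BB_ATOMS
  n <- dim(coords)[1]
  if (n < 1L) pd_stop("degenerate_input", "structure must contain >= 1 residue")
  if (!all(is.finite(coords))) pd_stop("degenerate_input", "non-finite coordinates")
  if (is.null(chain_lengths)) chain_lengths <- n
  chain_lengths <- as.integer(chain_lengths)
  if (sum(chain_lengths) != n)
    pd_stop("structural_mismatch", "chain lengths do not partition the residue range")
  if (is.null(chain_ids)) chain_ids <- LETTERS[seq_along(chain_lengths)]
  if (!is.null(sidechains)) stopifnot(length(sidechains) == n)
  structure(list(coords = coords, chain_lengths = chain_lengths,
                 chain_ids = chain_ids, sidechains = sidechains),
            class = "pd_structure")
}

BB_ATOMS <- c("N", "CA", "C", "O")

#' @export
print.pd_structure <- function(x, ...) {
  cat("<pd_structure> ", n_residues(x), " residues, ",
      length(x$chain_lengths), " chain(s) [",
      paste(x$chain_ids, collapse = ","), "]\n", sep = "")
  invisible(x)
}

#' Residue count of a structure
#' @param x A [pd_structure()].
#' @export
n_residues <- function(x) {
  stopifnot(inherits(x, "pd_structure"))
  dim(x$coords)[1]
}

#' Extract atom coordinates as a flat matrix
#'
#' @param x A [pd_structure()].
#' @param atoms Which atoms to select: a subset of `c("N","CA","C","O")`,
#'   `"backbone"` (all four), or `"CA"` (default).
#' @param residues Optional residue index subset.
#' @return Numeric matrix with 3 columns, rows ordered residue-major.
#' @export
atom_coords <- function(x, atoms = "CA", residues = NULL) {
  stopifnot(inherits(x, "pd_structure"))
  if (identical(atoms, "backbone")) atoms <- BB_ATOMS
  stopifnot(all(atoms %in% BB_ATOMS))
  if (is.null(residues)) residues <- seq_len(n_residues(x))
  sub <- x$coords[residues, atoms, , drop = FALSE]
  # residue-major flatten: residue 1 atoms, residue 2 atoms, ...
  out <- matrix(aperm(sub, c(2, 1, 3)), ncol = 3)
  colnames(out) <- c("x", "y", "z")
  out
}

#' All heavy-atom coordinates of one residue (backbone + side chain)
#' @keywords internal
residue_heavy_atoms <- function(x, i) {
  bb <- matrix(x$coords[i, , ], ncol = 3)
  if (!is.null(x$sidechains) && !is.null(x$sidechains[[i]]))
    bb <- rbind(bb, x$sidechains[[i]])
  bb
}

#' Build idealised backbone atoms around a CA trace
#'
#' Places N, C and O atoms in stylised positions using the local chain
#' direction and a local normal, so that the full backbone transforms
#' rigidly with the CA trace. Intended for synthetic structures; not a
#' substitute for real backbone geometry.
#'
#' @param ca Numeric `n x 3` matrix of CA coordinates.
#' @return `n x 4 x 3` backbone coordinate array.
#' @export
backbone_from_ca <- function(ca) {
  stopifnot(is.matrix(ca), ncol(ca) == 3L)
  n <- nrow(ca)
  tang <- matrix(0, n, 3)
  if (n == 1L) tang[1, ] <- c(1, 0, 0)
  else {
    tang[1, ] <- ca[2, ] - ca[1, ]
    tang[n, ] <- ca[n, ] - ca[n - 1, ]
    if (n > 2) tang[2:(n - 1), ] <- ca[3:n, ] - ca[1:(n - 2), ]
  }
  tang <- tang / pmax(sqrt(rowSums(tang^2)), 1e-9)
  # local normal: any vector not parallel to the tangent
  ref <- matrix(rep(c(0, 0, 1), each = n), n, 3)
  par <- abs(rowSums(tang * ref)) > 0.99
  ref[par, ] <- matrix(rep(c(0, 1, 0), sum(par)), ncol = 3, byrow = TRUE)
  nrm <- ref - tang * rowSums(tang * ref)
  nrm <- nrm / pmax(sqrt(rowSums(nrm^2)), 1e-9)
  co <- array(NA_real_, c(n, 4, 3), dimnames = list(NULL, BB_ATOMS, NULL))
  co[, "CA", ] <- ca
  co[, "N", ] <- ca - 1.46 * (0.8 * tang - 0.6 * nrm)
  co[, "C", ] <- ca + 1.52 * (0.8 * tang + 0.6 * nrm)
  co[, "O", ] <- co[, "C", ] + 1.23 * nrm
  co
}

#' Apply a rigid motion (rotation + translation) to a structure
#'
#' @param x A [pd_structure()].
#' @param rotation 3x3 proper rotation matrix.
#' @param translation Length-3 numeric vector.
#' @return The transformed structure.
#' @export
transform_structure <- function(x, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(inherits(x, "pd_structure"))
  stopifnot(all(dim(rotation) == c(3, 3)))
  flat <- matrix(x$coords, ncol = 3)
  flat <- flat %*% t(rotation) + matrix(translation, nrow(flat), 3, byrow = TRUE)
  co <- array(flat, dim(x$coords), dimnames = dimnames(x$coords))
  sc <- x$sidechains
  if (!is.null(sc)) {
    sc <- lapply(sc, function(m) {
      if (is.null(m)) return(NULL)
      m %*% t(rotation) + matrix(translation, nrow(m), 3, byrow = TRUE)
    })
  }
  pd_structure(co, x$chain_lengths, x$chain_ids, sc)
}

#' Structure ensemble (trajectory snapshots)
#'
#' An ordered list of [pd_structure()] objects over identical residues,
#' e.g. frames of a molecular-dynamics trajectory or NMR models.
#'
#' @param structures List of `pd_structure` with identical residue counts
#'   and chain maps.
#' @return Object of class `pd_ensemble`.
#' @export
pd_ensemble <- function(structures) {
  stopifnot(is.list(structures), length(structures) >= 1L)
  stopifnot(all(vapply(structures, inherits, TRUE, "pd_structure")))
  n <- vapply(structures, n_residues, 1L)
  if (length(unique(n)) != 1L)
    pd_stop("structural_mismatch", "ensemble members differ in residue count")
  cm <- lapply(structures, function(s) s$chain_lengths)
  if (!all(vapply(cm, identical, TRUE, cm[[1]])))
    pd_stop("structural_mismatch", "ensemble members differ in chain map")
  structure(list(structures = structures), class = "pd_ensemble")
}

#' @export
print.pd_ensemble <- function(x, ...) {
  cat("<pd_ensemble> ", length(x$structures), " snapshots x ",
      n_residues(x$structures[[1]]), " residues\n", sep = "")
  invisible(x)
}

#' @export
length.pd_ensemble <- function(x) length(x$structures)
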