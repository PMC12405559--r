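#' Structure file input/output
#'
#' Structures are exchanged as PDB (read/write, multi-model PDB read as
#' an ensemble) and mmCIF (read). Parsing is delegated to
#' \pkg{bio3d}; only backbone atoms (N, CA, C, O) are required, other
#' heavy atoms are collected per residue as side-chain coordinates.
#'
#' @param path File path.
#' @param x A [pd_structure()] to write.
#' @param sequence Optional [chained_seq()]; when given, residue names in
#'   the output PDB reflect the sequence.
#' @param b Optional per-residue B-factor column (e.g. pLDDT).
#' @return `read_structure_pdb()` / `read_structure_cif()` return a list
#'   with elements `structure` ([pd_structure()]) and `sequence`
#'   ([chained_seq()]); `read_ensemble_pdb()` returns a [pd_ensemble()].
#' @name structure_io
NULL

pdb_to_structure <- function(pdb) {
  at <- pdb$atom
  at <- at[at$type %in% c("ATOM", "HETATM") & !is.na(at$resno), , drop = FALSE]
  at <- at[at$type == "ATOM", , drop = FALSE]
  key <- paste(at$chain, at$resno, at$insert %||% "", sep = "_")
  ukey <- unique(key)
  n <- length(ukey)
  co <- array(NA_real_, c(n, 4, 3), dimnames = list(NULL, BB_ATOMS, NULL))
  side <- vector("list", n)
  res_chain <- character(n)
  res_aa <- character(n)
  idx <- split(seq_len(nrow(at)), factor(key, levels = ukey))
  for (i in seq_len(n)) {
    rows <- idx[[i]]
    sub <- at[rows, , drop = FALSE]
    res_chain[i] <- sub$chain[1]
    res_aa[i] <- sub$resid[1]
    for (a in BB_ATOMS) {
      hit <- which(sub$elety == a)
      if (length(hit))
        co[i, a, ] <- c(sub$x[hit[1]], sub$y[hit[1]], sub$z[hit[1]])
    }
    extra <- sub[!(sub$elety %in% c(BB_ATOMS, "OXT")) &
                   !grepl("^H", sub$elety), , drop = FALSE]
    if (nrow(extra))
      side[[i]] <- cbind(x = extra$x, y = extra$y, z = extra$z)
  }
  if (anyNA(co))
    pd_stop("structural_mismatch", "incomplete backbone (need N, CA, C, O per residue)")
  rle_chain <- rle(res_chain)
  aa1 <- suppressWarnings(bio3d::aa321(res_aa))
  aa1[is.na(aa1) | !(aa1 %in% AA_STANDARD)] <- AA_MASK
  lens <- rle_chain$lengths
  chains <- vapply(split(aa1, rep(seq_along(lens), lens)), paste, "",
                   collapse = "")
  if (all(is.na(rle_chain$values))) rle_chain$values <- LETTERS[seq_along(lens)]
  list(structure = pd_structure(co, chain_lengths = lens,
                                chain_ids = rle_chain$values,
                                sidechains = if (any(!vapply(side, is.null, TRUE))) side),
       sequence = chained_seq(unname(chains), chain_ids = rle_chain$values))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname structure_io
#' @export
read_structure_pdb <- function(path) {
  pdb_to_structure(bio3d::read.pdb(path, verbose = FALSE))
}

#' @rdname structure_io
#' @export
read_structure_cif <- function(path) {
  pdb_to_structure(bio3d::read.cif(path, verbose = FALSE))
}

#' @rdname structure_io
#' @export
read_ensemble_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  base <- pdb_to_structure(pdb)
  xyz <- pdb$xyz
  if (is.null(dim(xyz)) || nrow(xyz) == 1L) return(pd_ensemble(list(base$structure)))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  keep <- which(at$elety %in% BB_ATOMS)
  snaps <- lapply(seq_len(nrow(xyz)), function(m) {
    flat <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
    s <- base$structure
    key <- paste(at$chain, at$resno, sep = "_")
    ukey <- unique(key)
    co <- s$coords
    for (i in seq_along(ukey)) {
      rows <- which(key == ukey[i] & at$elety %in% BB_ATOMS)
      for (r in rows) co[i, at$elety[r], ] <- flat[r, ]
    }
    pd_structure(co, s$chain_lengths, s$chain_ids)
  })
  pd_ensemble(snaps)
}

#' @rdname structure_io
#' @export
write_structure_pdb <- function(x, path, sequence = NULL, b = NULL) {
  stopifnot(inherits(x, "pd_structure"))
  n <- n_residues(x)
  aa <- if (!is.null(sequence)) seq_chars(sequence) else rep("A", n)
  aa[aa == AA_MASK] <- "A"
  resid3 <- bio3d::aa123(aa)
  chain <- rep(x$chain_ids, x$chain_lengths)
  resno_in_chain <- unlist(lapply(x$chain_lengths, seq_len))
  if (is.null(b)) b <- rep(0, n)
  xyz <- numeric(0)
  elety <- character(0); resno <- integer(0); resid <- character(0)
  ch <- character(0); bb <- numeric(0)
  for (i in seq_len(n)) {
    for (a in BB_ATOMS) {
      xyz <- c(xyz, x$coords[i, a, ])
      elety <- c(elety, a)
      resno <- c(resno, resno_in_chain[i])
      resid <- c(resid, resid3[i])
      ch <- c(ch, chain[i])
      bb <- c(bb, b[i])
    }
  }
  bio3d::write.pdb(file = path, xyz = xyz, type = "ATOM", resno = resno,
                   resid = resid, elety = elety, chain = ch, b = bb,
                   o = rep(1, length(elety)))
  invisible(path)
}
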