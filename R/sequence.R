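#' Multi-chain amino-acid sequence
#'
#' A `chained_seq` holds one or more amino-acid chains (1-letter code)
#' together with chain labels and the allowed residue alphabet. All
#' residues must belong to the alphabet or be the mask sentinel
#' [AA_MASK]. Residue indexing is 1-based and contiguous over the
#' concatenated chains; chain boundaries are carried as closed index
#' intervals (see [chain_intervals()]).
#'
#' @param chains Character vector, one string per chain.
#' @param chain_ids Optional chain labels; defaults to `"A"`, `"B"`, ...
#' @param alphabet Allowed residue set (default [AA_STANDARD]).
#' @return An object of class `chained_seq`.
#' @examples
#' s <- chained_seq(c("MKV", "GG"))
#' seq_length(s)
#' chain_intervals(s)
#' @export
chained_seq <- function(chains, chain_ids = NULL, alphabet = AA_STANDARD) {
  stopifnot(is.character(chains), length(chains) >= 1L)
  if (is.null(chain_ids)) chain_ids <- LETTERS[seq_along(chains)]
  stopifnot(length(chain_ids) == length(chains), !anyDuplicated(chain_ids))
  nres <- nchar(chains)
  if (sum(nres) < 1L) pd_stop("degenerate_input", "total sequence length must be >= 1")
  ok <- unlist(strsplit(chains, "", fixed = TRUE)) %in% c(alphabet, AA_MASK)
  if (!all(ok)) {
    bad <- unique(unlist(strsplit(chains, "", fixed = TRUE))[!ok])
    pd_stop("unsupported_residue",
            paste0("residues outside alphabet: ", paste(bad, collapse = ", ")))
  }
  structure(list(chains = unname(chains), chain_ids = chain_ids,
                 alphabet = alphabet),
            class = "chained_seq")
}

#' @export
print.chained_seq <- function(x, ...) {
  cat("<chained_seq> ", length(x$chains), " chain(s), ",
      seq_length(x), " residues\n", sep = "")
  for (i in seq_along(x$chains))
    cat("  ", x$chain_ids[i], ": ", abbreviate_seq(x$chains[i]), "\n", sep = "")
  invisible(x)
}

abbreviate_seq <- function(s) {
  if (nchar(s) <= 60) s else paste0(substr(s, 1, 57), "...")
}

#' Total residue count of a chained sequence
#' @param x A [chained_seq()].
#' @return Integer.
#' @export
seq_length <- function(x) {
  stopifnot(inherits(x, "chained_seq"))
  sum(nchar(x$chains))
}

#' Chain boundaries as 1-based closed index intervals
#'
#' @param x A [chained_seq()] or a structure with a chain map.
#' @return A data.frame with columns `chain_id`, `start`, `end` over the
#'   concatenated residue index.
#' @export
chain_intervals <- function(x) {
  if (inherits(x, "pd_structure")) {
    lens <- x$chain_lengths
    ids <- x$chain_ids
  } else {
    stopifnot(inherits(x, "chained_seq"))
    lens <- nchar(x$chains)
    ids <- x$chain_ids
  }
  end <- cumsum(lens)
  data.frame(chain_id = ids, start = end - lens + 1L, end = end,
             stringsAsFactors = FALSE)
}

#' Concatenated residue characters of a chained sequence
#' @param x A [chained_seq()].
#' @return Character vector of single residues, length [seq_length()].
#' @export
seq_chars <- function(x) {
  stopifnot(inherits(x, "chained_seq"))
  unlist(strsplit(x$chains, "", fixed = TRUE), use.names = FALSE)
}

#' Residue indices belonging to given chains
#' @param x A [chained_seq()] or `pd_structure`.
#' @param chain_id Character vector of chain labels.
#' @return Integer vector of concatenated residue indices.
#' @export
chain_indices <- function(x, chain_id) {
  iv <- chain_intervals(x)
  rows <- match(chain_id, iv$chain_id)
  if (anyNA(rows)) pd_stop("invalid_chain", "unknown chain id")
  unlist(lapply(rows, function(r) seq.int(iv$start[r], iv$end[r])))
}

#' Read / write multi-chain sequences as FASTA
#'
#' Multi-chain sequences are stored as one FASTA record per chain with a
#' shared record-name prefix: `>name|chain`. Reading groups records back
#' into `chained_seq` objects by prefix.
#'
#' @param path File path.
#' @param x For writing: a named list of [chained_seq()] objects (names
#'   become record prefixes) or a single `chained_seq`.
#' @param name Record prefix when `x` is a single sequence.
#' @param alphabet Alphabet passed to [chained_seq()] when reading.
#' @return `read_chained_fasta()` returns a named list of `chained_seq`.
#' @export
read_chained_fasta <- function(path, alphabet = AA_STANDARD) {
  set <- Biostrings::readAAStringSet(path)
  nm <- names(set)
  prefix <- sub("\\|.*$", "", nm)
  chain <- ifelse(grepl("\\|", nm), sub("^[^|]*\\|", "", nm), "A")
  chain <- sub("\\s.*$", "", chain)
  out <- lapply(split(seq_along(set), factor(prefix, unique(prefix))), function(i) {
    chained_seq(as.character(set[i]), chain_ids = chain[i], alphabet = alphabet)
  })
  out
}

#' @rdname read_chained_fasta
#' @export
write_chained_fasta <- function(x, path, name = "design") {
  if (inherits(x, "chained_seq")) {
    x <- stats::setNames(list(x), name)
  }
  seqs <- character(0)
  for (nm in names(x)) {
    cs <- x[[nm]]
    s <- stats::setNames(cs$chains, paste0(nm, "|", cs$chain_ids))
    seqs <- c(seqs, s)
  }
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}
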