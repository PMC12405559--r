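#' Structure-conditioned sequence model contract
#'
#' A sequence model is a list of class `sequence_model` with a field
#' `probs`: a function `(chars, structure) -> n x 20 matrix` of
#' per-position categorical distributions over [AA_STANDARD] (rows sum
#' to 1), where `chars` is the working sequence with [AA_MASK] at
#' still-masked positions. The same `probs` evaluated on a fully
#' unmasked sequence provides exact per-residue likelihoods for
#' [score_likelihood()]. Models must be deterministic in their inputs.
#'
#' @param probs The distribution function described above.
#' @param name Model label.
#' @return Object of class `sequence_model`.
#' @export
sequence_model <- function(probs, name = "model") {
  stopifnot(is.function(probs))
  structure(list(probs = probs, name = name), class = "sequence_model")
}

#' Constraints applied during sequence redesign
#'
#' @param forbidden Globally forbidden residues (default `"C"`: cysteine
#'   is excluded from designed sequences).
#' @param forbidden_by_position Optional list mapping position index to
#'   extra forbidden residues at that position.
#' @param tied_groups Optional list of integer vectors; all positions in
#'   a group receive the sampled residue simultaneously (homooligomer /
#'   repeat ties). Groups must be disjoint.
#' @param frozen Named character vector or integer-indexed character
#'   vector of positions that keep a fixed residue (e.g. the target
#'   sequence in binder redesign); frozen positions are never masked.
#' @return Object of class `redesign_constraints`.
#' @export
redesign_constraints <- function(forbidden = "C", forbidden_by_position = list(),
                                 tied_groups = list(), frozen = NULL) {
  if (length(tied_groups) > 1L) {
    all_pos <- unlist(tied_groups)
    if (anyDuplicated(all_pos))
      pd_stop("invalid_config", "tied groups must be disjoint")
  }
  if (!is.null(frozen)) {
    stopifnot(!is.null(names(frozen)) || is.character(frozen))
  }
  structure(list(forbidden = forbidden,
                 forbidden_by_position = forbidden_by_position,
                 tied_groups = tied_groups, frozen = frozen),
            class = "redesign_constraints")
}

frozen_positions <- function(constraints) {
  if (is.null(constraints$frozen)) return(integer(0))
  as.integer(names(constraints$frozen))
}

#' Sample a sequence by masked autoregressive decoding
#'
#' Starting from a fully masked sequence (frozen positions excepted),
#' repeatedly: pick a still-masked position uniformly at random, query
#' the model's distribution there, zero out forbidden residues,
#' renormalise, sharpen by raising probabilities to the inverse
#' temperature (`p^beta`, renormalised; beta = 10 by default), sample a
#' residue, and write it to the position and all positions tied to it.
#' The model is re-queried after every committed residue, making the
#' procedure fully autoregressive.
#'
#' @param model A [sequence_model()].
#' @param structure The conditioning [pd_structure()].
#' @param constraints A [redesign_constraints()].
#' @param inv_temperature Sharpening exponent beta (default 10).
#' @param seed RNG seed.
#' @return List with `sequence` (string), `chars`, and `trace`
#'   (data.frame of per-step position/residue/probability).
#' @export
sample_sequence <- function(model, structure, constraints = redesign_constraints(),
                            inv_temperature = 10, seed = 1L) {
  stopifnot(inherits(model, "sequence_model"), inherits(structure, "pd_structure"))
  n <- n_residues(structure)
  chars <- rep(AA_MASK, n)
  froz <- frozen_positions(constraints)
  if (length(froz)) chars[froz] <- unname(constraints$frozen)
  masked <- setdiff(seq_len(n), froz)
  tie_of <- integer(n)
  for (g in seq_along(constraints$tied_groups))
    tie_of[constraints$tied_groups[[g]]] <- g
  trace <- vector("list", length(masked))
  step <- 0L
  with_local_seed(seed, {
    while (length(masked)) {
      pos <- masked[sample.int(length(masked), 1L)]
      pr <- model$probs(chars, structure)[pos, ]
      if (is.null(names(pr))) names(pr) <- AA_STANDARD
      forb <- union(constraints$forbidden,
                    constraints$forbidden_by_position[[as.character(pos)]])
      pr[names(pr) %in% forb] <- 0
      if (sum(pr) <= 0)
        pd_stop("unsatisfiable_constraint",
                paste0("all residues forbidden at position ", pos))
      pr <- pr / sum(pr)
      # sharpen in log space: p^beta can underflow for large beta
      lp <- inv_temperature * log(pr)
      lp <- lp - max(lp)
      pr <- exp(lp)
      pr <- pr / sum(pr)
      aa <- names(pr)[sample.int(length(pr), 1L, prob = pr)]
      targets <- if (tie_of[pos] > 0L)
        constraints$tied_groups[[tie_of[pos]]] else pos
      chars[targets] <- aa
      masked <- setdiff(masked, targets)
      step <- step + 1L
      trace[[step]] <- data.frame(step = step, position = pos, residue = aa,
                                  probability = unname(pr[aa]))
    }
  })
  list(sequence = paste(chars, collapse = ""), chars = chars,
       trace = do.call(rbind, trace[seq_len(step)]))
}

#' Mean log-likelihood of a sequence under a model
#'
#' `(1/N) sum_i log p(s_i | x)` in nats per residue, scored one-shot on
#' the fully unmasked sequence. A zero-probability residue yields `-Inf`
#' with attribute `zero_probability = TRUE`.
#'
#' @param model A [sequence_model()].
#' @param sequence Character string (or [chained_seq()]).
#' @param structure Conditioning [pd_structure()] of equal length.
#' @return Mean log-probability (nats/residue).
#' @export
score_likelihood <- function(model, sequence, structure) {
  if (inherits(sequence, "chained_seq")) sequence <- paste(sequence$chains, collapse = "")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (length(chars) != n_residues(structure))
    pd_stop("structural_mismatch", "sequence and structure lengths differ")
  pr <- model$probs(chars, structure)
  if (is.null(colnames(pr))) colnames(pr) <- AA_STANDARD
  p_i <- pr[cbind(seq_along(chars), match(chars, colnames(pr)))]
  if (any(is.na(p_i))) pd_stop("unsupported_residue", "residue not covered by model")
  if (any(p_i <= 0)) {
    out <- -Inf
    attr(out, "zero_probability") <- TRUE
    return(out)
  }
  mean(log(p_i))
}

#' Sample, deduplicate and likelihood-rank redesigns for a structure
#'
#' Draws `n_samples` sequences with [sample_sequence()] (100 by
#' default), removes duplicates, scores each unique sequence with
#' [score_likelihood()], and returns them ranked by likelihood,
#' descending; ties are broken by sampling order. Frozen positions are
#' identical to their constraint in every sample by construction.
#'
#' @inheritParams sample_sequence
#' @param n_samples Number of samples (default 100).
#' @return data.frame with columns `sequence`, `loglik`, `n_drawn`,
#'   `rank`, ordered by rank.
#' @export
redesign_batch <- function(model, structure, constraints = redesign_constraints(),
                           n_samples = 100L, inv_temperature = 10, seed = 1L) {
  seqs <- vapply(seq_len(n_samples), function(k) {
    sample_sequence(model, structure, constraints, inv_temperature,
                    seed = seed + k - 1L)$sequence
  }, "")
  first <- !duplicated(seqs)
  uniq <- seqs[first]
  counts <- as.integer(table(factor(seqs, levels = uniq)))
  ll <- vapply(uniq, function(s) as.numeric(score_likelihood(model, s, structure)), 1)
  ord <- order(-ll, seq_along(uniq))
  data.frame(sequence = uniq[ord], loglik = ll[ord], n_drawn = counts[ord],
             rank = seq_along(ord), row.names = NULL)
}

#' Reference structure-conditioned profile model
#'
#' A deterministic stand-in sequence model computed from backbone
#' features only: per-position burial (CA neighbour count within
#' `burial_radius`) interpolates each position's distribution between a
#' hydrophobic-leaning core profile and a polar/charged-leaning surface
#' profile, smoothed to full support over the 20 residues. Because the
#' features are pairwise-distance based, the model is invariant under
#' rigid motion of the structure.
#'
#' @param structure A [pd_structure()] with backbone coordinates.
#' @param burial_radius CA neighbour radius in Angstrom (default 10).
#' @param smoothing Uniform mass mixed in for full support (default 0.02).
#' @return A [sequence_model()].
#' @export
reference_profile_model <- function(structure, burial_radius = 10,
                                    smoothing = 0.02) {
  stopifnot(inherits(structure, "pd_structure"))
  ca <- atom_coords(structure, "CA")
  d <- as.matrix(stats::dist(ca))
  nb <- rowSums(d < burial_radius) - 1L
  burial <- if (max(nb) > min(nb)) (nb - min(nb)) / (max(nb) - min(nb))
            else rep(0.5, length(nb))
  core <- c(A = 2, L = 3, I = 2.5, V = 2.5, F = 2, M = 1.5, W = 1, Y = 1,
            G = 0.3, T = 0.5, S = 0.4)
  surf <- c(E = 2.5, K = 2.5, R = 2, D = 2, Q = 1.5, N = 1.5, S = 1.2,
            T = 1, H = 0.8, G = 0.5, A = 0.8, P = 0.3, Y = 0.4)
  to_profile <- function(w) {
    p <- stats::setNames(numeric(length(AA_STANDARD)), AA_STANDARD)
    p[names(w)] <- w
    p / sum(p)
  }
  core_p <- to_profile(core)
  surf_p <- to_profile(surf)
  unif <- rep(1 / length(AA_STANDARD), length(AA_STANDARD))
  mat <- t(vapply(burial, function(b) {
    p <- b * core_p + (1 - b) * surf_p
    p <- (1 - smoothing) * p + smoothing * unif
    p / sum(p)
  }, core_p))
  colnames(mat) <- AA_STANDARD
  sequence_model(function(chars, structure) mat, name = "reference_profile")
}
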