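#' Design-task fitness specification
#'
#' Collects the weights and thresholds of the composite fitness
#' functions: the confidence mixing weight `alpha`, the site-distance
#' threshold `r` (Angstrom), the radius-of-gyration threshold `R`
#' (Angstrom; when `NULL`, the globular scaling `2.2 N^0.38` is used for
#' the evaluated part), the conformational-change ceiling `tm_max` and
#' the predictor's `pae_max`. Chain roles name which chains are being
#' designed (`designed`) and which belong to a fixed target (`target`).
#'
#' @param task One of `"denovo"`, `"binder"`, `"change"`, `"custom"`.
#' @param alpha Confidence mixing weight in \[0, 1\] (default 0.7 for
#'   de novo and binder tasks).
#' @param r Site-distance threshold (Angstrom, > 0; default 6).
#' @param R Radius-of-gyration threshold (Angstrom, > 0) or `NULL` for
#'   the length-scaled default.
#' @param tm_max Maximal tolerated TM-score between states in \[0, 1\].
#' @param pae_max pAE normalisation ceiling (Angstrom).
#' @param site Target-site residue indices (within the target chain).
#' @param designed,target Chain ids of designed and fixed-target chains.
#' @return Object of class `fitness_spec`.
#' @export
fitness_spec <- function(task = c("denovo", "binder", "change", "custom"),
                         alpha = 0.7, r = 6, R = NULL, tm_max = 0.5,
                         pae_max = 31.75, site = integer(0),
                         designed = NULL, target = NULL) {
  task <- match.arg(task)
  if (alpha < 0 || alpha > 1) pd_stop("invalid_spec", "alpha outside [0, 1]")
  if (r <= 0) pd_stop("invalid_spec", "r must be positive")
  if (!is.null(R) && R <= 0) pd_stop("invalid_spec", "R must be positive")
  if (tm_max < 0 || tm_max > 1) pd_stop("invalid_spec", "tm_max outside [0, 1]")
  structure(list(task = task, alpha = alpha, r = r, R = R, tm_max = tm_max,
                 pae_max = pae_max, site = as.integer(site),
                 designed = designed, target = target),
            class = "fitness_spec")
}

#' Length-scaled default radius-of-gyration threshold
#'
#' Empirical globular compactness law `R = 2.2 N^0.38` Angstrom, used
#' when a fitness spec does not fix `R` explicitly.
#'
#' @param n Residue count.
#' @return Threshold in Angstrom.
#' @export
default_rg_threshold <- function(n) 2.2 * n^0.38

resolve_part <- function(p, part) {
  if (is.null(part)) return(seq_len(n_residues(p$structure)))
  if (is.character(part)) return(chain_indices(p$structure, part))
  part <- as.integer(part)
  if (!length(part)) pd_stop("degenerate_input", "empty part")
  if (any(part < 1L | part > n_residues(p$structure)))
    pd_stop("degenerate_input", "part indices out of range")
  part
}

#' Confidence fitness terms
#'
#' The three confidence components evaluated over a residue subset of a
#' prediction, each in \[0, 1\]:
#' `l_pae = 1 - mean(pAE)/pae_max` over the part-by-part block,
#' `l_plddt = mean(pLDDT)/100` (pLDDT is normalised to \[0, 1\] before it
#' is mixed additively with `l_pae`), and their average
#' `l_conf = (l_pae + l_plddt)/2`.
#'
#' @param p A [pd_prediction()].
#' @param part Residue indices or chain ids (default: all residues).
#' @return Named list `l_pae`, `l_plddt`, `l_conf`.
#' @export
confidence_terms <- function(p, part = NULL) {
  stopifnot(inherits(p, "pd_prediction"))
  idx <- resolve_part(p, part)
  block <- p$pae[idx, idx, drop = FALSE]
  if (any(block > p$pae_max + 1e-9)) pd_stop("range_error", "pAE exceeds pae_max")
  l_pae <- 1 - mean(block) / p$pae_max
  l_plddt <- mean(p$plddt[idx]) / 100
  list(l_pae = l_pae, l_plddt = l_plddt, l_conf = (l_pae + l_plddt) / 2)
}

#' Interface confidence term
#'
#' `1 - mean(pAE over the two off-diagonal blocks)/pae_max` for two
#' disjoint residue parts; tracks predicted interaction confidence.
#'
#' @param p A [pd_prediction()].
#' @param x_part,y_part Disjoint, non-empty residue parts (indices or
#'   chain ids).
#' @return Scalar in \[0, 1\].
#' @export
ipae_term <- function(p, x_part, y_part) {
  stopifnot(inherits(p, "pd_prediction"))
  xi <- resolve_part(p, x_part)
  yi <- resolve_part(p, y_part)
  if (length(intersect(xi, yi)))
    pd_stop("partition_error", "x_part and y_part overlap")
  vals <- c(p$pae[xi, yi], p$pae[yi, xi])
  1 - mean(vals) / p$pae_max
}

#' Aligned-error transfer function
#'
#' `f(d) = 1/(1 + d/d0)` as used by [approx_tm_term()] (default, the
#' form as printed in the fitness table), or the canonical squared form
#' `1/(1 + (d/d0)^2)` when `squared = TRUE`. `f(0) = 1`, `f(d0) = 1/2`
#' in both forms.
#'
#' @param d Aligned error (Angstrom).
#' @param d0 Normalisation length (see [tm_d0()]).
#' @param squared Use the squared form.
#' @return Value in (0, 1].
#' @export
tm_transfer <- function(d, d0, squared = FALSE) {
  if (squared) 1 / (1 + (d / d0)^2) else 1 / (1 + d / d0)
}

#' Approximate template-matching score between two conformations
#'
#' Compares the conformation of the same chain in two predictions via
#' the aligned-error construction ([aligned_error()]):
#' `max_j mean_i f(AE_ij)` with `f(d) = 1/(1 + d/d0)` as the default
#' transfer function (set `squared = TRUE` for the canonical
#' `1/(1 + (d/d0)^2)` form) and the standard d0 for the part length.
#' Used to score conformational change between bound and unbound states.
#'
#' @param p_x,p_xy Predictions containing the chain in its two states.
#' @param x_part Residue part of the chain in `p_x`.
#' @param xy_part Residue part of the same chain in `p_xy` (defaults to
#'   `x_part`).
#' @param squared Use the squared transfer function (default `FALSE`).
#' @return Scalar in (0, 1]; 1 for identical conformations.
#' @export
approx_tm_term <- function(p_x, p_xy, x_part = NULL, xy_part = x_part,
                           squared = FALSE) {
  stopifnot(inherits(p_x, "pd_prediction"), inherits(p_xy, "pd_prediction"))
  xi <- resolve_part(p_x, x_part)
  yi <- resolve_part(p_xy, xy_part)
  if (length(xi) != length(yi))
    pd_stop("structural_mismatch", "parts differ in residue count")
  sa <- subset_structure(p_x$structure, xi)
  sb <- subset_structure(p_xy$structure, yi)
  ae <- aligned_error(sa, sb)
  max(colMeans(tm_transfer(ae, tm_d0(length(xi)), squared)))
}

# single-chain view of a residue subset
subset_structure <- function(s, idx) {
  pd_structure(s$coords[idx, , , drop = FALSE], chain_lengths = length(idx),
               chain_ids = s$chain_ids[1],
               sidechains = if (!is.null(s$sidechains)) s$sidechains[idx])
}

#' Site-distance penalty
#'
#' `max(r, min_i d(X_i, T_s)) - r`: zero while any binder residue's CA
#' lies within `r` Angstrom of the target site, growing linearly with
#' the shortfall otherwise.
#'
#' @param p A [pd_prediction()] of the binder-target complex.
#' @param binder_part Binder residue part (indices or chain ids).
#' @param site Target-site residue indices (global indices in `p`).
#' @param r Distance threshold in Angstrom (default 6).
#' @return Penalty >= 0.
#' @export
site_distance_penalty <- function(p, binder_part, site, r = 6) {
  stopifnot(inherits(p, "pd_prediction"))
  bi <- resolve_part(p, binder_part)
  site <- resolve_part(p, site)
  ca <- atom_coords(p$structure, "CA")
  d <- min_pair_dist(ca[bi, , drop = FALSE], ca[site, , drop = FALSE])
  max(r, d) - r
}

#' Radius-of-gyration penalty
#'
#' `(max(R, Rg) - R)/R`: zero for parts at least as compact as the
#' threshold, scaling linearly in the relative excess otherwise.
#'
#' @param p A [pd_prediction()].
#' @param part Residue part (default: all residues).
#' @param R Threshold in Angstrom; `NULL` for [default_rg_threshold()]
#'   of the part length.
#' @return Penalty >= 0.
#' @export
radius_penalty <- function(p, part = NULL, R = NULL) {
  stopifnot(inherits(p, "pd_prediction"))
  idx <- resolve_part(p, part)
  if (is.null(R)) R <- default_rg_threshold(length(idx))
  if (R <= 0) pd_stop("invalid_spec", "R must be positive")
  rg <- radius_of_gyration(p$structure, "CA", idx)
  (max(R, rg) - R) / R
}

#' Composite design fitness
#'
#' Evaluates the published composite fitness for the task in `spec`:
#'
#' * `denovo`: `2 (alpha L_conf(X1:...:XN) + (1 - alpha) mean_i L_conf(X^i)) - L_R`,
#'   with the per-chain confidence terms taken on the joint prediction
#'   restricted to each chain.
#' * `binder`: `L_bind - L_site - L_R(X)` where
#'   `L_bind = alpha L_ipAE(X, T) + (1 - alpha) L_conf(X)`.
#' * `change`: `alpha L_conf(X:Y) + (1 - alpha) L_conf(X) -
#'   ReLU(L_TM(X, X_in_X:Y) - tm_max)`.
#'
#' @param spec A [fitness_spec()].
#' @param predictions Named list of [pd_prediction()] objects: `complex`
#'   for all tasks; additionally `monomer` for the `change` task.
#' @return Scalar fitness (larger is better).
#' @export
composite_fitness <- function(spec, predictions) {
  stopifnot(inherits(spec, "fitness_spec"))
  if (inherits(predictions, "pd_prediction"))
    predictions <- list(complex = predictions)
  need <- switch(spec$task, denovo = "complex", binder = "complex",
                 change = c("monomer", "complex"),
                 custom = pd_stop("invalid_spec",
                                  "custom tasks supply their own fitness function"))
  missing <- setdiff(need, names(predictions))
  if (length(missing))
    pd_stop("incomplete_task",
            paste("missing prediction state(s):", paste(missing, collapse = ", ")))
  cx <- predictions$complex
  switch(spec$task,
    denovo = {
      all_conf <- confidence_terms(cx)$l_conf
      per_chain <- vapply(cx$structure$chain_ids,
                          function(id) confidence_terms(cx, id)$l_conf, 1)
      2 * (spec$alpha * all_conf + (1 - spec$alpha) * mean(per_chain)) -
        radius_penalty(cx, R = spec$R)
    },
    binder = {
      x <- spec$designed %||% cx$structure$chain_ids[1]
      t <- spec$target %||% setdiff(cx$structure$chain_ids, x)
      if (!length(t)) pd_stop("incomplete_task", "binder task needs a target chain")
      l_bind <- spec$alpha * ipae_term(cx, x, t) +
        (1 - spec$alpha) * confidence_terms(cx, x)$l_conf
      site_global <- chain_indices(cx$structure, t[1])[spec$site]
      l_site <- if (length(spec$site))
        site_distance_penalty(cx, x, site_global, r = spec$r) else 0
      l_bind - l_site - radius_penalty(cx, x, R = spec$R)
    },
    change = {
      mono <- predictions$monomer
      x <- spec$designed %||% mono$structure$chain_ids[1]
      l_tm <- approx_tm_term(mono, cx, x_part = NULL,
                             xy_part = chain_indices(cx$structure, x))
      spec$alpha * confidence_terms(cx)$l_conf +
        (1 - spec$alpha) * confidence_terms(mono)$l_conf -
        max(l_tm - spec$tm_max, 0)
    })
}
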