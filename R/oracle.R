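#' Structure fragment used as a prediction template
#'
#' A template pins part of a chain during prediction: the oracle must
#' return coordinates for the mapped residues that match the template.
#' The index map records where each fragment residue sits in the full
#' target chain (strictly increasing, 1-based).
#'
#' @param sequence Fragment sequence (single string).
#' @param structure Fragment [pd_structure()] of equal length.
#' @param index_map Strictly increasing integer vector of source residue
#'   indices into the full chain.
#' @return Object of class `pd_template`.
#' @export
pd_template <- function(sequence, structure, index_map) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            inherits(structure, "pd_structure"))
  index_map <- as.integer(index_map)
  if (nchar(sequence) != n_residues(structure) ||
      length(index_map) != n_residues(structure))
    pd_stop("structural_mismatch", "template sequence/structure/index map lengths differ")
  if (any(diff(index_map) <= 0L))
    pd_stop("degenerate_input", "template index map must be strictly increasing")
  structure(list(sequence = sequence, structure = structure,
                 index_map = index_map), class = "pd_template")
}

#' Crop a target structure around a binding site
#'
#' Selects the `budget` residues whose CA atoms are spatially nearest to
#' the centroid of the site residues, always including the site itself,
#' and returns them as a [pd_template()] preserving the original residue
#' index map. Cropping keeps the prediction cost of binder design fixed
#' regardless of target size.
#'
#' @param structure Full-target [pd_structure()] (single chain).
#' @param sequence Matching [chained_seq()] (or a single string).
#' @param site Residue indices of the binding site.
#' @param budget Number of residues to keep; must be at least `length(site)`.
#' @return A [pd_template()] of exactly `budget` residues.
#' @export
crop_target <- function(structure, sequence, site, budget) {
  stopifnot(inherits(structure, "pd_structure"))
  if (inherits(sequence, "chained_seq")) sequence <- paste(sequence$chains, collapse = "")
  n <- n_residues(structure)
  stopifnot(nchar(sequence) == n)
  site <- as.integer(site)
  if (any(site < 1L | site > n)) pd_stop("degenerate_input", "site indices out of range")
  if (budget < length(site))
    pd_stop("invalid_budget", "budget smaller than the site itself")
  budget <- min(budget, n)
  ca <- atom_coords(structure, "CA")
  ctr <- colMeans(ca[site, , drop = FALSE])
  d <- sqrt(rowSums(sweep(ca, 2, ctr)^2))
  d[site] <- -Inf                      # site residues always win
  keep <- sort(order(d)[seq_len(budget)])
  frag_co <- structure$coords[keep, , , drop = FALSE]
  frag <- pd_structure(frag_co, chain_lengths = length(keep),
                       chain_ids = structure$chain_ids[1])
  pd_template(paste(strsplit(sequence, "")[[1]][keep], collapse = ""),
              frag, keep)
}

#' Prediction request for a structure oracle
#'
#' @param sequence A [chained_seq()].
#' @param templates Optional named list of [pd_template()] keyed by chain
#'   id; template chains must exist in the sequence.
#' @param recycle_count Number of recycling iterations requested (>= 0).
#' @param init_structure Optional [pd_structure()] used to initialise
#'   recycling (e.g. the designed complex during validation).
#' @return Object of class `oracle_request`.
#' @export
oracle_request <- function(sequence, templates = NULL, recycle_count = 0L,
                           init_structure = NULL) {
  stopifnot(inherits(sequence, "chained_seq"), recycle_count >= 0)
  if (!is.null(templates)) {
    stopifnot(is.list(templates), !is.null(names(templates)))
    if (!all(names(templates) %in% sequence$chain_ids))
      pd_stop("invalid_chain", "template chain label not present in sequence")
    lens <- nchar(sequence$chains)[match(names(templates), sequence$chain_ids)]
    for (k in seq_along(templates)) {
      stopifnot(inherits(templates[[k]], "pd_template"))
      if (max(templates[[k]]$index_map) > lens[k])
        pd_stop("structural_mismatch", "template index map exceeds chain length")
    }
  }
  if (!is.null(init_structure)) stopifnot(inherits(init_structure, "pd_structure"))
  structure(list(sequence = sequence, templates = templates,
                 recycle_count = as.integer(recycle_count),
                 init_structure = init_structure),
            class = "oracle_request")
}

#' Default residue folding propensities of the synthetic oracle
#'
#' A fixed map from residue type to a helix-forming/foldability score in
#' \[0, 1\], loosely shaped like experimental helix-propensity scales
#' (alanine highest; glycine and proline strong breakers). The synthetic
#' landscape derives every confidence output from windowed means of
#' these scores.
#'
#' @return Named numeric vector over the 20 standard residues.
#' @export
default_propensity <- function() {
  c(A = 1.00, L = 0.90, M = 0.85, E = 0.85, K = 0.80, R = 0.80, Q = 0.80,
    I = 0.75, W = 0.75, D = 0.72, F = 0.72, V = 0.70, Y = 0.70, H = 0.70,
    S = 0.68, N = 0.65, T = 0.62, C = 0.60, G = 0.30, P = 0.15)
}

#' Deterministic synthetic structure-prediction oracle
#'
#' A stand-in for a neural structure predictor that satisfies the full
#' prediction contract at negligible cost, so design loops, benchmarks
#' and tests run without any trained network. Per-residue pLDDT is a
#' smooth (windowed) function of residue propensity scores
#' ([default_propensity()]); pAE grows with sequence separation and
#' shrinks with the confidence of the flanking residues; coordinates
#' follow an idealised curled helix/coil trace in which high-propensity
#' windows form helices. All outputs are deterministic in
#' (request, oracle seed). Templated residues are pinned: their output
#' coordinates equal the template coordinates exactly.
#'
#' @param seed Oracle seed (determines coil-trace jitter streams).
#' @param pae_max pAE ceiling in Angstrom (default 31.75).
#' @param window Propensity smoothing window (residues, default 5).
#' @param helix_threshold Windowed-propensity level above which a residue
#'   is traced as helix (default 0.5).
#' @param sep_floor Fraction of the maximal pAE retained at zero
#'   sequence separation (default 0.2).
#' @param chain_gap Inter-chain offset of the synthetic trace (Angstrom).
#' @param curl_radius Radius of the global trace curl (Angstrom).
#' @param alphabet Residues the oracle accepts.
#' @return Object of class `synthetic_folder`; pass to
#'   [predict_structure()].
#' @export
synthetic_folder <- function(seed = 1L, pae_max = 31.75, window = 5L,
                             helix_threshold = 0.5, sep_floor = 0.2,
                             chain_gap = 9, curl_radius = 40,
                             alphabet = AA_STANDARD) {
  state <- new.env(parent = emptyenv())
  state$cache <- new.env(parent = emptyenv())
  state$calls <- 0L
  state$cache_hits <- 0L
  structure(list(seed = as.integer(seed), pae_max = pae_max,
                 window = as.integer(window),
                 helix_threshold = helix_threshold, sep_floor = sep_floor,
                 chain_gap = chain_gap, curl_radius = curl_radius,
                 propensity = default_propensity(), alphabet = alphabet,
                 state = state),
            class = c("synthetic_folder", "pd_oracle"))
}

#' @export
print.synthetic_folder <- function(x, ...) {
  cat(sprintf("<synthetic_folder> seed %d | pae_max %.2f | %d calls (%d cache hits)\n",
              x$seed, x$pae_max, x$state$calls, x$state$cache_hits))
  invisible(x)
}

#' Oracle call statistics
#' @param oracle A `synthetic_folder`.
#' @return List with `calls` (predictions computed) and `cache_hits`.
#' @export
oracle_stats <- function(oracle) {
  list(calls = oracle$state$calls, cache_hits = oracle$state$cache_hits)
}

# windowed mean with truncated edges
windowed_mean <- function(x, window) {
  n <- length(x)
  half <- window %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

request_key <- function(oracle, req) {
  tpl <- ""
  if (!is.null(req$templates)) {
    tpl <- paste(vapply(names(req$templates), function(id) {
      t <- req$templates[[id]]
      paste(id, paste(t$index_map, collapse = ","),
            paste(round(as.numeric(t$structure$coords), 3), collapse = ","),
            sep = ":")
    }, ""), collapse = ";")
  }
  paste(oracle$seed, paste(req$sequence$chain_ids, collapse = ","),
        paste(req$sequence$chains, collapse = "/"), req$recycle_count, tpl,
        sep = "|")
}

#' Run a structure-prediction oracle
#'
#' Evaluates an [oracle_request()] and returns a [pd_prediction()]
#' satisfying all prediction invariants. Results are cached on a
#' canonical request key, since design loops repeatedly re-evaluate
#' sequences. `predict_batch()` maps over a list of requests.
#'
#' @param oracle A `synthetic_folder` (or any object with a
#'   `predict_structure` method).
#' @param request An [oracle_request()] (or a [chained_seq()], wrapped
#'   with default request settings).
#' @return A [pd_prediction()].
#' @export
predict_structure <- function(oracle, request) {
  UseMethod("predict_structure")
}

#' @rdname predict_structure
#' @param requests List of requests for `predict_batch()`.
#' @export
predict_batch <- function(oracle, requests) {
  lapply(requests, function(r) predict_structure(oracle, r))
}

#' @export
predict_structure.synthetic_folder <- function(oracle, request) {
  if (inherits(request, "chained_seq")) request <- oracle_request(request)
  stopifnot(inherits(request, "oracle_request"))
  key <- request_key(oracle, request)
  if (!is.null(oracle$state$cache[[key]])) {
    oracle$state$cache_hits <- oracle$state$cache_hits + 1L
    return(oracle$state$cache[[key]])
  }
  cs <- request$sequence
  chars <- seq_chars(cs)
  if (any(!(chars %in% oracle$alphabet)))
    pd_stop("unsupported_residue",
            paste0("residue(s) outside oracle alphabet: ",
                   paste(unique(chars[!(chars %in% oracle$alphabet)]), collapse = ", ")))
  lens <- nchar(cs$chains)
  p <- oracle$propensity[chars]
  # per-chain windowed propensity
  q <- unlist(lapply(split(p, rep(seq_along(lens), lens)), windowed_mean,
                     window = oracle$window), use.names = FALSE)
  q <- pmin(pmax(q, 0), 1)   # guard cumulative-sum rounding at the extremes
  n <- length(q)
  plddt <- 100 * q
  sep <- abs(outer(seq_len(n), seq_len(n), "-")) / max(n - 1L, 1L)
  minq <- outer(q, q, pmin)
  pae <- oracle$pae_max * (1 - minq) *
    (oracle$sep_floor + (1 - oracle$sep_floor) * sep)
  diag(pae) <- 0
  # trace coordinates, chain by chain
  co <- array(NA_real_, c(n, 4, 3), dimnames = list(NULL, BB_ATOMS, NULL))
  offset <- 0L
  for (ci in seq_along(lens)) {
    idx <- offset + seq_len(lens[ci])
    helix <- q[idx] >= oracle$helix_threshold
    jseed <- (oracle$seed + 7919L * ci +
                str_hash31(cs$chains[ci])) %% 2147483647
    ca <- synthetic_trace(helix, oracle$curl_radius, jseed)
    ca[, 2] <- ca[, 2] + (ci - 1L) * oracle$chain_gap
    co[idx, , ] <- backbone_from_ca(ca)
    offset <- offset + lens[ci]
  }
  # template pinning: hard overwrite of mapped residues
  if (!is.null(request$templates)) {
    iv <- chain_intervals(cs)
    for (id in names(request$templates)) {
      t <- request$templates[[id]]
      gstart <- iv$start[match(id, iv$chain_id)]
      gidx <- gstart + t$index_map - 1L
      co[gidx, , ] <- t$structure$coords
      plddt[gidx] <- pmax(plddt[gidx], 90)
    }
  }
  struct <- pd_structure(co, chain_lengths = lens, chain_ids = cs$chain_ids)
  pred <- pd_prediction(struct, plddt, pae, ptm_from_pae(pae),
                        pae_max = oracle$pae_max)
  oracle$state$calls <- oracle$state$calls + 1L
  oracle$state$cache[[key]] <- pred
  pred
}

# CA trace: curled arc axis; helical offset for helix residues,
# seeded jitter for coil residues. Deterministic in (helix mask, seed).
synthetic_trace <- function(helix, curl_radius, seed) {
  n <- length(helix)
  rise <- ifelse(helix, 1.5, 3.2)
  arc <- cumsum(c(0, rise[-n])) / curl_radius
  axis <- curl_radius * cbind(sin(arc), 0, 1 - cos(arc))
  normal <- cbind(-cos(arc), 0, -sin(arc))   # points toward the curl centre
  binorm <- matrix(rep(c(0, 1, 0), each = n), n, 3)
  theta <- cumsum(c(0, rep(100 * pi / 180, n - 1)))
  jit <- with_local_seed(seed, matrix(stats::runif(2 * n, -1.5, 1.5), n, 2))
  off_r <- ifelse(helix, 2.3 * cos(theta), jit[, 1])
  off_b <- ifelse(helix, 2.3 * sin(theta), jit[, 2])
  axis + normal * off_r + binorm * off_b
}
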