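#' Toxin-inhibition colony-screen analysis
#'
#' Plates are 16 x 24 (384-position) colony arrays carried as
#' long-format data.frames with one row per position and columns
#' `plate`, `condition` (`none`, `arabinose`, `iptg`, `both`),
#' `bio_rep` (recipient biological replicate), `row`, `col`, `strain`,
#' `donor_rep` (donor biological replicate), `tech_rep`, `opacity` and
#' `edge`. Strains matching `gfp_pattern` are the non-blocking
#' negative controls (32 positions per plate in the default layout).
#'
#' @name tic
NULL

TIC_CONDITIONS <- c("none", "arabinose", "iptg", "both")

#' Default 384-array screen layout
#'
#' Mirrors the pinning geometry of a robotic colony screen: a 96-well
#' donor library (88 blockers + 8 GFP control wells, each present as 2
#' donor biological replicates x 2 technical replicates) re-arrayed
#' into a 16 x 24 grid. Outermost rows/columns are flagged as edge
#' positions. GFP controls therefore occupy 32 positions per plate.
#'
#' @param n_blockers Number of blocker strains (default 88).
#' @param n_gfp Number of GFP control wells (default 8).
#' @param seed Seed for the within-plate position shuffle.
#' @return data.frame with columns `row`, `col`, `strain`, `donor_rep`,
#'   `tech_rep`, `edge`.
#' @export
tic_layout <- function(n_blockers = 88L, n_gfp = 8L, seed = 101L) {
  n_wells <- n_blockers + n_gfp
  stopifnot(4L * n_wells == 384L)
  wells <- c(sprintf("blocker_%02d", seq_len(n_blockers)),
             sprintf("GFP_%d", seq_len(n_gfp)))
  unit <- expand.grid(well = wells, donor_rep = 1:2, tech_rep = 1:2,
                      stringsAsFactors = FALSE)
  pos <- expand.grid(row = 1:16, col = 1:24)
  ord <- with_local_seed(seed, sample.int(384L))
  data.frame(row = pos$row[ord], col = pos$col[ord],
             strain = unit$well, donor_rep = unit$donor_rep,
             tech_rep = unit$tech_rep,
             edge = pos$row[ord] %in% c(1L, 16L) | pos$col[ord] %in% c(1L, 24L),
             stringsAsFactors = FALSE)
}

#' Simulate a toxin-inhibition screen
#'
#' Generates opacity tables for all four induction conditions across
#' recipient biological replicates, with log-normal colony noise,
#' toxin-mediated growth suppression on arabinose, planted
#' multiplicative blocker effects on double induction, optional leaky
#' (blocker active without induction) and toxic (blocker itself
#' impairing growth) strains, inflated edge positions, and a fraction
#' of pinning misses (opacity 0). Ground-truth labels are attached as
#' the `truth` attribute.
#'
#' @param layout Plate layout from [tic_layout()].
#' @param effects Named numeric vector of planted blocker effects
#'   (multiplier on double-induction fitness; 1 = null). Missing
#'   blockers default to 1; GFP controls are always 1.
#' @param n_bio Recipient biological replicates (default 3).
#' @param sigma Log-normal noise standard deviation (default 0.1).
#' @param base_opacity Median colony opacity without toxin (default 1000).
#' @param toxin_survival Growth fraction under toxin induction (default 0.3).
#' @param edge_factor Multiplicative edge inflation (default 1.25).
#' @param miss_rate Pinning-miss probability per position (default 0.01).
#' @param leaky,toxic Optional character vectors of blocker names that
#'   are leaky (effect applies on arabinose-only plates too) or toxic
#'   (growth reduced to `toxic_survival` on blocker-only induction).
#' @param toxic_survival Growth fraction of toxic blockers under IPTG.
#' @param seed RNG seed.
#' @return Long-format data.frame (see [tic]); attribute `truth` holds
#'   the planted effect per blocker.
#' @export
simulate_screen <- function(layout = tic_layout(), effects = NULL,
                            n_bio = 3L, sigma = 0.1, base_opacity = 1000,
                            toxin_survival = 0.3, edge_factor = 1.25,
                            miss_rate = 0.01, leaky = character(0),
                            toxic = character(0), toxic_survival = 0.4,
                            seed = 1L) {
  stopifnot(sigma > 0)
  blockers <- unique(layout$strain[!grepl("^GFP", layout$strain)])
  eff <- stats::setNames(rep(1, length(blockers)), blockers)
  if (!is.null(effects)) eff[names(effects)] <- effects
  plates <- list()
  with_local_seed(seed, {
    for (b in seq_len(n_bio)) {
      for (cond in TIC_CONDITIONS) {
        mu <- rep(base_opacity, nrow(layout))
        is_gfp <- grepl("^GFP", layout$strain)
        e <- ifelse(is_gfp, 1, eff[layout$strain])
        if (cond %in% c("arabinose", "both")) mu <- mu * toxin_survival
        if (cond == "both") mu <- mu * e
        if (cond == "arabinose") {
          lk <- layout$strain %in% leaky
          mu[lk] <- mu[lk] * e[lk]
        }
        if (cond %in% c("iptg", "both")) {
          tx <- layout$strain %in% toxic
          mu[tx] <- mu[tx] * toxic_survival
        }
        op <- mu * exp(stats::rnorm(nrow(layout), 0, sigma))
        op[layout$edge] <- op[layout$edge] * edge_factor
        op[stats::runif(nrow(layout)) < miss_rate] <- 0
        plates[[length(plates) + 1L]] <-
          data.frame(plate = sprintf("%s_bio%d", cond, b), condition = cond,
                     bio_rep = b, layout, opacity = op,
                     stringsAsFactors = FALSE)
      }
    }
  })
  out <- do.call(rbind, plates)
  rownames(out) <- NULL
  attr(out, "truth") <- list(effects = eff, leaky = leaky, toxic = toxic)
  out
}

#' Preprocess one plate: pinning misses and edge correction
#'
#' Positions with opacity exactly 0 are flagged as pinning misses
#' (excluded from all downstream statistics). Edge positions, which run
#' systematically more opaque, are rescaled by the single multiplicative
#' factor `median(interior) / median(edge)` computed from non-missing
#' colonies.
#'
#' @param plate Long-format rows of a single plate.
#' @return The plate with a logical `missing` column and corrected
#'   opacities.
#' @export
preprocess_plate <- function(plate) {
  stopifnot(all(c("opacity", "edge") %in% names(plate)))
  if (length(unique(plate$plate %||% "p")) > 1L)
    pd_stop("invalid_config", "preprocess_plate expects a single plate")
  plate$missing <- plate$opacity == 0
  if (all(plate$missing)) pd_stop("empty_plate", "all positions are pinning misses")
  med_in <- stats::median(plate$opacity[!plate$edge & !plate$missing])
  med_edge <- stats::median(plate$opacity[plate$edge & !plate$missing])
  if (isTRUE(med_edge > 0)) {
    f <- med_in / med_edge
    plate$opacity[plate$edge & !plate$missing] <-
      plate$opacity[plate$edge & !plate$missing] * f
  }
  plate
}

#' Normalised fitness per strain replicate
#'
#' Divides each colony's opacity by the mean opacity of the GFP
#' controls on the same plate, then averages the technical replicates,
#' giving one normalised fitness value per
#' (strain, donor replicate, condition, recipient replicate).
#'
#' @param screen Long-format screen data (any number of plates);
#'   preprocessed per plate via [preprocess_plate()] if not already.
#' @param gfp_pattern Regular expression identifying control strains.
#' @return data.frame with columns `strain`, `donor_rep`, `condition`,
#'   `bio_rep`, `fitness`.
#' @export
normalize_fitness <- function(screen, gfp_pattern = "^GFP") {
  if (!("missing" %in% names(screen))) {
    screen <- do.call(rbind, lapply(split(screen, screen$plate), preprocess_plate))
  }
  screen <- screen[!screen$missing, , drop = FALSE]
  norm <- lapply(split(screen, screen$plate), function(p) {
    gfp <- grepl(gfp_pattern, p$strain)
    if (!any(gfp)) pd_stop("normalization_error", "no valid GFP controls on plate")
    p$fitness <- p$opacity / mean(p$opacity[gfp])
    p
  })
  screen <- do.call(rbind, norm)
  agg <- stats::aggregate(fitness ~ strain + donor_rep + condition + bio_rep,
                          data = screen, FUN = mean)
  rownames(agg) <- NULL
  agg
}

#' Per-blocker induction effects
#'
#' The effect of a blocker replicate is the ratio of its normalised
#' fitness under double induction (toxin + blocker; `both`) to its
#' fitness under toxin-only induction (`arabinose`). Blocker effects
#' are computed per (donor replicate x recipient replicate); GFP
#' control effects are computed per control strain from fitness
#' averaged across recipient replicates, defining the null sample.
#' Replicates with a missing or zero denominator are flagged undefined
#' and excluded.
#'
#' @param fitness Output of [normalize_fitness()].
#' @param gfp_pattern Regular expression identifying control strains.
#' @return List with `blockers` (data.frame `strain`, `donor_rep`,
#'   `bio_rep`, `effect`) and `gfp` (numeric vector of control
#'   effects).
#' @export
blocker_effect <- function(fitness, gfp_pattern = "^GFP") {
  is_gfp <- grepl(gfp_pattern, fitness$strain)
  bl <- fitness[!is_gfp, , drop = FALSE]
  wide <- merge(bl[bl$condition == "both",
                   c("strain", "donor_rep", "bio_rep", "fitness")],
                bl[bl$condition == "arabinose",
                   c("strain", "donor_rep", "bio_rep", "fitness")],
                by = c("strain", "donor_rep", "bio_rep"),
                suffixes = c("_both", "_ara"))
  wide$undefined <- is.na(wide$fitness_ara) | wide$fitness_ara <= 0
  wide$effect <- ifelse(wide$undefined, NA_real_,
                        wide$fitness_both / wide$fitness_ara)
  gf <- fitness[is_gfp & fitness$condition %in% c("both", "arabinose"), ,
                drop = FALSE]
  gmean <- stats::aggregate(fitness ~ strain + donor_rep + condition,
                            data = gf, FUN = mean)  # average recipient reps
  gw <- merge(gmean[gmean$condition == "both", c("strain", "donor_rep", "fitness")],
              gmean[gmean$condition == "arabinose", c("strain", "donor_rep", "fitness")],
              by = c("strain", "donor_rep"), suffixes = c("_both", "_ara"))
  gfp_eff <- gw$fitness_both / gw$fitness_ara
  list(blockers = wide[!wide$undefined,
                       c("strain", "donor_rep", "bio_rep", "effect")],
       gfp = gfp_eff[is.finite(gfp_eff)])
}

welch_p <- function(x, y) {
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  stats::t.test(x, y, var.equal = FALSE)$p.value
}

#' Score blockers against the GFP null
#'
#' For each blocker: a two-sided Welch unequal-variance t-test of its
#' effects (n = donor x recipient replicates) against the pooled GFP
#' control effects; a cumulative effect size, the mean blocker effect
#' divided by the mean GFP effect; and the hit call
#' `p < p_cutoff & effect size > effect_cutoff`. Leaky blockers grow
#' above `mean + 2 SD` of the GFP controls on toxin-only plates; toxic
#' blockers fall below `mean - 2 SD` of the controls on blocker-only
#' (IPTG) plates.
#'
#' @param effects Output of [blocker_effect()].
#' @param fitness Output of [normalize_fitness()] (for leaky/toxic
#'   flags); optional.
#' @param effect_cutoff Effect-size cutoff (default 1.1; use 1.3 for
#'   the harder-to-inhibit toxin homologue).
#' @param p_cutoff Significance cutoff (default 0.01).
#' @param gfp_pattern Regular expression identifying control strains.
#' @return data.frame (`blocker_result`) with one row per blocker:
#'   `strain`, `n`, `effect_size`, `t_p`, `hit`, `leaky`, `toxic`.
#' @export
test_blockers <- function(effects, fitness = NULL, effect_cutoff = 1.1,
                          p_cutoff = 0.01, gfp_pattern = "^GFP") {
  gfp <- effects$gfp
  if (length(gfp) < 2L) pd_stop("invalid_config", "need >= 2 GFP control effects")
  gfp_mean <- mean(gfp)
  leak_tox <- NULL
  if (!is.null(fitness)) {
    is_gfp <- grepl(gfp_pattern, fitness$strain)
    band <- function(cond) {
      g <- fitness$fitness[is_gfp & fitness$condition == cond]
      c(mean = mean(g), sd = stats::sd(g))
    }
    ara <- band("arabinose"); iptg <- band("iptg")
    per <- stats::aggregate(fitness ~ strain + condition,
                            data = fitness[!is_gfp, ], FUN = mean)
    leak_tox <- list(
      leaky = per$strain[per$condition == "arabinose" &
                           per$fitness > ara["mean"] + 2 * ara["sd"]],
      toxic = per$strain[per$condition == "iptg" &
                           per$fitness < iptg["mean"] - 2 * iptg["sd"]])
  }
  rows <- lapply(split(effects$blockers, effects$blockers$strain), function(b) {
    e <- b$effect
    if (length(e) < 2L) {
      return(data.frame(strain = b$strain[1], n = length(e),
                        effect_size = mean(e) / gfp_mean, t_p = NA_real_,
                        hit = NA, stringsAsFactors = FALSE))
    }
    p <- welch_p(e, gfp)
    es <- mean(e) / gfp_mean
    data.frame(strain = b$strain[1], n = length(e), effect_size = es,
               t_p = p, hit = p < p_cutoff & es > effect_cutoff,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$leaky <- if (!is.null(leak_tox)) out$strain %in% leak_tox$leaky else NA
  out$toxic <- if (!is.null(leak_tox)) out$strain %in% leak_tox$toxic else NA
  class(out) <- c("blocker_result", class(out))
  out
}

#' Full screen analysis pipeline
#'
#' Preprocess every plate, normalise fitness to the GFP controls,
#' compute induction effects and score blockers.
#'
#' @inheritParams normalize_fitness
#' @inheritParams test_blockers
#' @return A `blocker_result` data.frame (see [test_blockers()]).
#' @export
tic_analyze <- function(screen, effect_cutoff = 1.1, p_cutoff = 0.01,
                        gfp_pattern = "^GFP") {
  fitness <- normalize_fitness(screen, gfp_pattern)
  eff <- blocker_effect(fitness, gfp_pattern)
  test_blockers(eff, fitness, effect_cutoff, p_cutoff, gfp_pattern)
}
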