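#' Approximate E. coli K-12 codon usage
#'
#' Default codon usage table: per-family relative codon fractions,
#' approximating the E. coli K-12 bias. Intended as a sensible default
#' for reverse translation; supply your own table (same columns) for
#' other hosts or exact frequencies.
#'
#' @return data.frame with columns `aa` (1-letter), `codon` (DNA,
#'   uppercase) and `fraction` (relative usage within the synonymous
#'   family, summing to 1 per residue).
#' @export
ecoli_codon_usage <- function() {
  tab <- c(
    "A GCG 0.36", "A GCC 0.27", "A GCA 0.21", "A GCT 0.16",
    "R CGC 0.40", "R CGT 0.38", "R CGG 0.10", "R CGA 0.06", "R AGA 0.04", "R AGG 0.02",
    "N AAC 0.55", "N AAT 0.45",
    "D GAT 0.63", "D GAC 0.37",
    "C TGC 0.55", "C TGT 0.45",
    "Q CAG 0.65", "Q CAA 0.35",
    "E GAA 0.69", "E GAG 0.31",
    "G GGC 0.40", "G GGT 0.34", "G GGG 0.15", "G GGA 0.11",
    "H CAT 0.57", "H CAC 0.43",
    "I ATT 0.51", "I ATC 0.42", "I ATA 0.07",
    "L CTG 0.50", "L TTA 0.13", "L TTG 0.13", "L CTT 0.10", "L CTC 0.10", "L CTA 0.04",
    "K AAA 0.76", "K AAG 0.24",
    "M ATG 1.00",
    "F TTT 0.57", "F TTC 0.43",
    "P CCG 0.52", "P CCA 0.19", "P CCT 0.16", "P CCC 0.12",
    "S AGC 0.28", "S TCT 0.15", "S TCC 0.15", "S AGT 0.15", "S TCG 0.15", "S TCA 0.12",
    "T ACC 0.44", "T ACG 0.27", "T ACT 0.17", "T ACA 0.13",
    "W TGG 1.00",
    "Y TAT 0.57", "Y TAC 0.43",
    "V GTG 0.37", "V GTT 0.26", "V GTC 0.22", "V GTA 0.15")
  parts <- strsplit(tab, " ", fixed = TRUE)
  data.frame(aa = vapply(parts, `[`, "", 1),
             codon = vapply(parts, `[`, "", 2),
             fraction = as.numeric(vapply(parts, `[`, "", 3)),
             stringsAsFactors = FALSE)
}

gc_content <- function(dna) {
  chars <- strsplit(dna, "", fixed = TRUE)[[1]]
  mean(chars %in% c("G", "C"))
}

revcomp <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

has_tandem_pentamer <- function(dna) {
  n <- nchar(dna)
  if (n < 10L) return(FALSE)
  chars <- strsplit(dna, "", fixed = TRUE)[[1]]
  for (i in seq_len(n - 9L)) {
    if (all(chars[i:(i + 4L)] == chars[(i + 5L):(i + 9L)])) return(TRUE)
  }
  FALSE
}

find_hairpin <- function(dna, stem = 10L, window = 60L) {
  n <- nchar(dna)
  if (n < 2L * stem) return(NULL)
  for (i in seq_len(n - 2L * stem + 1L)) {
    s <- substr(dna, i, i + stem - 1L)
    rc <- revcomp(s)
    lo <- i + stem
    hi <- min(n, i + window - 1L)
    if (hi - lo + 1L < stem) next
    hit <- regexpr(rc, substr(dna, lo, hi), fixed = TRUE)
    if (hit > 0) return(c(stem_start = i, pair_start = lo + as.integer(hit) - 1L))
  }
  NULL
}

#' Check reverse-translated DNA against design constraints
#'
#' Independent constraint checker for coding sequences: exact
#' back-translation to the input protein, global GC content within
#' bounds, no rare codons (relative usage below `rare_cutoff` within a
#' family), no tandem pentanucleotide repeat (a 5-mer immediately
#' repeated), and no hairpin (a perfect reverse-complement stem pair of
#' at least `hairpin_stem` nt within a `hairpin_window` nt window).
#'
#' @param dna Coding DNA sequence (no stop codon).
#' @param protein Expected protein sequence, or `NULL` to skip.
#' @param usage Codon usage table (see [ecoli_codon_usage()]).
#' @param gc_min,gc_max GC bounds (defaults 0.35, 0.65).
#' @param rare_cutoff Rare-codon fraction cutoff (default 0.1).
#' @param hairpin_stem,hairpin_window Hairpin geometry (defaults 10, 60).
#' @return List of logical checks plus `gc`, `violations` and `ok`.
#' @export
check_dna_constraints <- function(dna, protein = NULL,
                                  usage = ecoli_codon_usage(),
                                  gc_min = 0.35, gc_max = 0.65,
                                  rare_cutoff = 0.1,
                                  hairpin_stem = 10L, hairpin_window = 60L) {
  stopifnot(nchar(dna) %% 3 == 0)
  codons <- substring(dna, seq(1, nchar(dna), 3), seq(3, nchar(dna), 3))
  trans <- as.character(Biostrings::translate(Biostrings::DNAString(dna)))
  res <- list()
  res$translates <- is.null(protein) || identical(trans, protein)
  res$gc <- gc_content(dna)
  res$gc_ok <- res$gc >= gc_min && res$gc <= gc_max
  rare <- usage$codon[usage$fraction < rare_cutoff]
  res$no_rare <- !any(codons %in% rare)
  res$no_tandem_pentamer <- !has_tandem_pentamer(dna)
  res$no_hairpin <- is.null(find_hairpin(dna, hairpin_stem, hairpin_window))
  checks <- c(translates = res$translates, gc = res$gc_ok, rare = res$no_rare,
              tandem_pentamer = res$no_tandem_pentamer, hairpin = res$no_hairpin)
  res$violations <- names(checks)[!checks]
  res$ok <- !length(res$violations)
  res
}

#' Reverse-translate and codon-optimise a protein sequence
#'
#' Produces a coding DNA sequence that translates back exactly to the
#' input, with codons drawn toward the usage table, subject to: global
#' GC in `[gc_min, gc_max]`, no rare codons, no tandem pentanucleotide
#' repeats and no hairpin-forming sub-sequences (see
#' [check_dna_constraints()] for the definitions). Sampling is
#' deterministic given `(sequence, seed)`. Codons are sampled
#' position-by-position with local repeat screening, then GC is
#' repaired by synonymous swaps if needed; if the constraints cannot be
#' satisfied after `max_restarts` seeded attempts, an error lists the
#' violated constraints.
#'
#' @param protein Protein sequence (string over the 20 standard
#'   residues) or a [chained_seq()] (chains concatenated).
#' @param usage Codon usage table (see [ecoli_codon_usage()]).
#' @param seed RNG seed.
#' @inheritParams check_dna_constraints
#' @param max_restarts Seeded sampling attempts before giving up.
#' @return DNA string of length `3 * nchar(protein)`.
#' @export
codon_optimize <- function(protein, usage = ecoli_codon_usage(), seed = 1L,
                           gc_min = 0.35, gc_max = 0.65, rare_cutoff = 0.1,
                           hairpin_stem = 10L, hairpin_window = 60L,
                           max_restarts = 50L) {
  if (inherits(protein, "chained_seq")) protein <- paste(protein$chains, collapse = "")
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  if (any(!(aa %in% AA_STANDARD)))
    pd_stop("unsupported_residue", "protein contains non-standard residues")
  allowed <- usage[usage$fraction >= rare_cutoff, , drop = FALSE]
  by_aa <- split(allowed, allowed$aa)
  if (any(!(aa %in% names(by_aa))))
    pd_stop("invalid_config", "usage table lacks allowed codons for some residue")
  last <- NULL
  for (attempt in seq_len(max_restarts)) {
    dna <- with_local_seed(seed + 977L * (attempt - 1L),
                           sample_coding(aa, by_aa))
    if (is.null(dna)) next
    dna <- repair_gc(dna, aa, by_aa, gc_min, gc_max)
    last <- check_dna_constraints(dna, protein, usage, gc_min, gc_max,
                                  rare_cutoff, hairpin_stem, hairpin_window)
    if (last$ok) return(dna)
  }
  pd_stop("constraint_failure",
          paste0("codon optimisation failed after ", max_restarts,
                 " attempts; violated: ",
                 paste(last$violations %||% "sampling", collapse = ", ")))
}

# one seeded sampling pass with local tandem-repeat screening
sample_coding <- function(aa, by_aa) {
  out <- character(length(aa))
  built <- ""
  for (i in seq_along(aa)) {
    fam <- by_aa[[aa[i]]]
    ord <- sample.int(nrow(fam), nrow(fam), prob = fam$fraction)
    placed <- FALSE
    for (k in ord) {
      cand <- paste0(substr(built, max(1, nchar(built) - 9L), nchar(built)),
                     fam$codon[k])
      if (!has_tandem_pentamer(cand)) {
        out[i] <- fam$codon[k]
        built <- paste0(built, fam$codon[k])
        placed <- TRUE
        break
      }
    }
    if (!placed) return(NULL)
  }
  paste(out, collapse = "")
}

# synonymous swaps toward the GC band, largest GC delta first,
# skipping swaps that would introduce a tandem repeat
repair_gc <- function(dna, aa, by_aa, gc_min, gc_max) {
  codon_gc <- function(c3) sum(strsplit(c3, "")[[1]] %in% c("G", "C"))
  for (pass in seq_len(2L * length(aa))) {
    gc <- gc_content(dna)
    if (gc >= gc_min && gc <= gc_max) break
    dir <- if (gc < gc_min) 1L else -1L
    codons <- substring(dna, seq(1, nchar(dna), 3), seq(3, nchar(dna), 3))
    best <- NULL; best_delta <- 0L
    for (i in seq_along(aa)) {
      fam <- by_aa[[aa[i]]]
      cur_gc <- codon_gc(codons[i])
      for (k in seq_len(nrow(fam))) {
        delta <- dir * (codon_gc(fam$codon[k]) - cur_gc)
        if (delta > best_delta) {
          trial <- codons; trial[i] <- fam$codon[k]
          trial_dna <- paste(trial, collapse = "")
          lo <- max(1L, 3L * i - 11L); hi <- min(nchar(trial_dna), 3L * i + 11L)
          if (!has_tandem_pentamer(substr(trial_dna, lo, hi))) {
            best <- list(i = i, codon = fam$codon[k]); best_delta <- delta
          }
        }
      }
    }
    if (is.null(best)) break
    codons[best$i] <- best$codon
    dna <- paste(codons, collapse = "")
  }
  dna
}
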