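---
title: "Hallucination-based protein design: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hallucination-based protein design: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protdesign)
```

## The design problem

Hallucination-based protein design treats a structure predictor as an
oracle: instead of asking "what structure does this sequence fold
into", it searches sequence space for inputs the predictor folds with
high confidence, possibly subject to geometric constraints. The
predictor's confidence outputs are the currency of the whole pipeline:

* **pLDDT** — per-residue confidence on a 0–100 scale;
* **pAE** — an $n \times n$ matrix (Å) of predicted aligned error: the
  expected positional error of residue $i$ when the prediction is
  aligned on residue $j$'s local frame. Its inter-chain blocks (ipAE)
  track interaction confidence;
* **pTM** — a global predicted TM-score in $[0, 1]$.

`protdesign` implements the full loop around such an oracle — fitness
composition, evolutionary search, masked autoregressive sequence
redesign, self-consistency validation, codon optimisation, and the
statistics of the downstream in vivo colony screen — with the neural
predictor and the sequence model behind pluggable contracts, and
deterministic synthetic stand-ins for both so that everything runs at
desk scale.

## Fitness algebra

All design goals are expressed through a small algebra over
predictions (`confidence_terms()`, `ipae_term()`, `approx_tm_term()`,
`site_distance_penalty()`, `radius_penalty()`), combined by
`composite_fitness()`:

* $L_{pAE}(X) = 1 - \operatorname{mean}(pAE(X)) / pAE_{max}$,
* $L_{pLDDT}(X) = \operatorname{mean}(pLDDT(X)) / 100$,
* $L_{conf} = (L_{pAE} + L_{pLDDT}) / 2$,
* $L_{ipAE}(X, Y) = 1 - \operatorname{mean}(pAE \text{ over the two
  off-diagonal blocks}) / pAE_{max}$,
* $L_{site}(X \mid T; r, s) = \max(r, \min_i d(X_i, T_s)) - r$ with CA
  distances and $r = 6$ Å by default,
* $L_R(X; R) = (\max(R, R_g) - R) / R$,
* $L_{TM}(X, X') = \max_j \operatorname{mean}_i f(AE_{ij})$ with
  $f(d) = 1 / (1 + d / d_0)$ and
  $d_0 = 1.24\,(\max(L, 19) - 15)^{1/3} - 1.8$.

Composites: de novo design maximises
$2\,(\alpha L_{conf}(X^1{:}\dots{:}X^N) + (1-\alpha)\,
\overline{L_{conf}(X^i)}) - L_R$; binder design maximises
$\alpha L_{ipAE}(X, T) + (1-\alpha) L_{conf}(X) - L_{site} - L_R(X)$;
conformational-change design maximises
$\alpha L_{conf}(X{:}Y) + (1-\alpha) L_{conf}(X) -
\mathrm{ReLU}(L_{TM} - TM_{max})$. The mixing weight defaults to
$\alpha = 0.7$.

Design choices worth making explicit:

* **pLDDT normalisation.** $L_{conf}$ mixes $L_{pAE}$ and $L_{pLDDT}$
  additively; an unnormalised 0–100 pLDDT would swamp the pAE term, so
  pLDDT is divided by 100 first. The same convention makes the
  validation filter $pLDDT \cdot pTM < 0.5$ meaningful (on a 0–100
  scale that threshold would never fire).
* **The transfer function $f$.** The form $1/(1 + d/d_0)$ is used as
  the default; the canonical squared TM weight $1/(1 + (d/d_0)^2)$ is
  available via `squared = TRUE` in `approx_tm_term()` /
  `tm_transfer()`. Both satisfy $f(0) = 1$ and $f(d_0) = 1/2$.
* **Aligned error between two observed structures.** pAE is defined
  for a prediction against an unknown truth; between two concrete
  conformations of the same chain we define $AE_{ij}$ as the distance
  between residue $i$'s CA in the two structures after expressing both
  in residue $j$'s local backbone frame (Gram–Schmidt on CA→C and
  CA→N). This reduces to the pAE construction when one structure is
  the prediction target. An alternative reading via distance-matrix
  differences would be rotation-free but was not adopted.
* **Per-chain confidence in the de novo composite.** The per-chain
  terms $L_{conf}(X^i)$ are evaluated on the joint complex prediction
  restricted to chain $i$ (pAE submatrix, pLDDT subvector), not on
  separate monomer predictions: one oracle call per pool member is
  what makes the evolutionary loop affordable.
* **Compactness threshold.** When `R` is not set explicitly the
  globular scaling $R = 2.2\,N^{0.38}$ Å is used. Worked examples in
  this package use an explicit `R = 15` Å for 30-residue single
  helices, where the globular law is tighter than the synthetic
  oracle's geometry can satisfy.
* **Indexing.** Residue indices are 1-based and contiguous over
  concatenated chains, with chain boundaries as closed intervals —
  the natural convention for matrix slicing in R.

## The evolutionary hallucination loop

`run_design()` maintains a pool (default size 10) of sequences,
initialised i.i.d. uniform over a cysteine-free alphabet (cysteines
complicate recombinant expression). Each step draws parents uniformly
from the *eligible* set — members whose fitness lies within the
suboptimality band, $f \ge f_{best} - 0.1\,|f_{best}|$ by default —
and proposes children by point substitution, with the substitution
count Poisson(1) conditioned on being at least one. Survivors are the
top `population_size` of parents and children combined (elitist
$\mu{+}\lambda$), so best-so-far fitness is non-decreasing by
construction. The fitness band (rather than a rank band) is one of two
defensible readings of "suboptimality"; it is recorded here and kept
configurable through `evolve_config()`. Recombination is off: with a
smooth windowed landscape, point mutation plus elitism suffices and
keeps runs bit-reproducible from a single seed. Every evaluation is
cached on the sequence, so re-visited sequences cost nothing; the
evaluation budget counts oracle calls, not proposals. Oracle recycling
defaults to 2 steps during design and 4 during validation.

## The synthetic folding oracle

`synthetic_folder()` is a deterministic stand-in for a neural
structure predictor. Each residue type carries a fixed propensity
score in $[0, 1]$ (`default_propensity()`, shaped like experimental
helix-propensity scales: alanine 1.0, glycine 0.30, proline 0.15);
the per-residue landscape value $q_i$ is the mean propensity over a
5-residue window. Then

* $pLDDT_i = 100\,q_i$;
* $pAE_{ij} = pAE_{max}\,(1 - \min(q_i, q_j))
  \,(0.2 + 0.8\,|i - j| / (n - 1))$, zero on the diagonal;
* pTM is reduced from the pAE matrix by the standard
  $\max_j \operatorname{mean}_i 1/(1 + (pAE_{ij}/d_0)^2)$;
* coordinates follow an idealised trace along a gently curled axis
  (radius 40 Å): residues with $q_i \ge 0.5$ get ideal helix geometry
  (radius 2.3 Å, rise 1.5 Å, 100°/residue), the rest a seeded coil
  wiggle. Chains are laid 9 Å apart.

$pAE_{max}$ defaults to 31.75 Å, the usual error-bin ceiling of
structure predictors, and is surfaced to the fitness module. Templated
residues (see below) are pinned: their output coordinates equal the
template's exactly, and their pLDDT is floored at 90.

This landscape is smooth (single mutations move fitness by a bounded
amount), admits hill climbing, rewards the same residues a real
predictor tends to reward, and satisfies every prediction invariant —
which is exactly what the design loop, the redesign stage and the
validation stage need from an oracle to be testable end to end. What
it does **not** emulate: real folding physics, adversarial sequences,
sequence-nonlocal epistasis, multi-domain packing, or any correlation
structure between pLDDT and pAE beyond the shared $q$. Passing tests
against this oracle therefore validate the *machinery* (search,
sampling, selection, statistics), not the biological success rates one
would obtain with a trained predictor, which require GPU-scale models.
Adapters for real predictors implement the same
`predict_structure()` contract. The synthetic oracle ignores the
requested recycle count numerically (outputs are already fixed points
of recycling); the count is still carried in the request and cache
key, as real adapters do use it.

### Templates and target cropping

For binder design against a fixed target, the target's structure is
supplied as a template (`pd_template`) and pinned during prediction —
a hard pin, which is the strictest reading of template conditioning;
soft template features in real predictors may deviate slightly.
`crop_target()` reduces prediction cost by keeping only the `budget`
residues nearest (CA distance) to the binding-site centroid, always
including the site, with the original index map preserved.

## Masked autoregressive sequence redesign

High-fitness sequences found by hallucination tend to be adversarial
for the very predictor that scored them, and express poorly. The
redesign stage replaces them with native-like sequences for the *same*
backbone. `sample_sequence()` starts from a fully masked sequence
(frozen regions excepted, e.g. the target chain of a binder) and
iterates: pick a masked position uniformly at random; query the
sequence model's distribution there; zero forbidden residues and
renormalise; sharpen with an inverse temperature of 10 (probabilities
raised to $\beta$ and renormalised — identical to logit scaling, and
computed in log space so large $\beta$ cannot underflow); sample;
write the residue to the position and all tied positions (the
homooligomer/repeat mechanism); repeat until no masks remain. The
model is re-queried after every committed residue, i.e. decoding is
fully autoregressive rather than one-shot.

`redesign_batch()` draws 100 sequences by default, deduplicates, and
ranks by `score_likelihood()` — the mean per-residue log-probability
of the complete sequence (one-shot conditioning on the empty mask;
chain-rule accumulation along the sampling path would score the
*trajectory* rather than the sequence and is intentionally not the
default). Ties are broken by sampling order so rankings are
reproducible.

The built-in `reference_profile_model()` is a deterministic,
structure-conditioned profile: burial (CA neighbour count within
10 Å) interpolates each position between a hydrophobic-leaning core
profile and a polar/charged surface profile, smoothed to full support.
It is invariant under rigid motion (features are pairwise distances)
and serves as the default sequence model; trained inverse-folding
models plug in through the same two-function `sequence_model()`
contract.

## Validation, selection and gene synthesis

`self_consistency()` re-predicts each (re)designed sequence (4
recycles; binder tasks pass the target template and initialise
recycling with the designed complex) and measures scRMSD (CA Kabsch
RMSD between raw and re-predicted structures), scTM, mean pLDDT/pAE,
ipAE and pTM, one record per oracle. Classification uses strict
inequalities exactly: *lax* success is $pLDDT > 70 \wedge scRMSD <
2$ Å; *strict* success (binders) adds $pLDDT > 80 \wedge scRMSD < 1$ Å
$\wedge\ ipAE < 10$ Å; boundary values fail. Multi-state designs are
benchmarked once per state; states are combined conjunctively (every
state must pass), the conservative reading, configurable by filtering
records per state. `select_best()` applies all thresholds first and
then minimises scRMSD, breaking ties by design id so the choice is
order-invariant.

`filter_cascade()` applies the candidate gates in fixed order: drop if
mean log-likelihood $< -0.1$ nats/residue; drop if $pLDDT \cdot pTM <
0.5$ (pLDDT on $[0,1]$); drop if a solubility score is provided and is
below 1 — solubility prediction is an external hook, recorded as "not
evaluated" when absent.

`codon_optimize()` reverse-translates survivors for expression:
codons are drawn toward a usage table (an approximate E. coli K-12
table ships as the default; any table with the same columns works),
excluding rare codons (relative family usage below 10%), tandem
pentanucleotide repeats (a 5-mer immediately repeated), hairpins
(perfect reverse-complement stem pairs of ≥ 10 nt within a 60 nt
window — both parameters are configuration, since "hairpin-forming"
is not a single number), and global GC outside 35–65%. The sampler
screens repeats as it extends, repairs GC by synonymous swaps, and
restarts from a derived seed if needed; the independent
`check_dna_constraints()` validates every output.

## Colony-screen statistics

The in vivo readout is a toxin-inhibition conjugation screen: colonies
carrying an inducible toxin and an inducible designed blocker are
arrayed on 16×24 (384-position) plates under four induction conditions
(none / toxin / blocker / both), and colony opacity proxies fitness.
The analysis follows the screen's standard pipeline:

1. `preprocess_plate()`: opacity 0 is a pinning miss (excluded);
   outer-edge colonies, which run systematically denser, are rescaled
   by the single factor median(interior)/median(edge).
2. `normalize_fitness()`: each colony is divided by the mean of the 32
   GFP control positions on its own plate, and technical replicates
   are averaged. Per-plate normalisation makes the pipeline exactly
   invariant to rescaling any whole plate.
3. `blocker_effect()`: a blocker's effect is its normalised fitness
   under double induction divided by its fitness under toxin-only
   induction, per replicate — 6 values (2 donor × 3 recipient
   biological replicates) per blocker.
4. `test_blockers()`: a two-sided Welch unequal-variance t-test
   against the pooled GFP effects, an effect size equal to the mean
   blocker effect over the mean GFP effect, and the hit rule
   $p < 0.01 \wedge \text{effect} > 1.1$ (1.3 for the harder toxin
   homologue; the cutoff is strict `>`). Leaky blockers exceed
   mean + 2 SD of the controls on toxin-only plates; toxic blockers
   fall below mean − 2 SD on blocker-only plates.

One replication detail is under-determined by the replicate counts
alone: with 8 GFP library wells × 2 donor replicates × 2 technical
replicates on every plate, a GFP null sample of size 16 arises only if
each control's effect is computed from fitness averaged across the 3
recipient replicates. That grouping is adopted here (16 control
strains, one effect each); blocker effects keep per-recipient
resolution (n = 6). The grouping is a function argument away from
other conventions.

`simulate_screen()` generates the whole design — log-normal colony
noise (σ = 0.1 by default), toxin survival 0.3, edge inflation 1.25,
1% pinning misses, planted multiplicative blocker effects, optional
leaky/toxic strains — with ground truth attached, so calibration
(type I error at the published cutoffs, power against planted 1.5×
effects, unbiasedness of the effect estimate) is measured rather than
assumed. It does not model spatial autocorrelation beyond the edge
effect, plate-to-plate batch trends, or colony-size/opacity
nonlinearity from image quantification.

## Numerical choices and degenerate inputs

* Superposition uses SVD-based Kabsch with the determinant correction
  (no reflections — chirality is physical); two points are accepted
  (the problem is still well-posed), one is not.
* `tm_score()` maximises the score over superpositions by iterating
  Kabsch fits weighted with the TM weights, keeping the best score
  seen; $d_0$ is clamped to ≥ 0.5 Å so short chains keep a positive
  scale. No structural alignment search is performed — residue
  correspondence is always the identity.
* Ensemble RMSF aligns snapshots to the ensemble mean over two
  refinement passes (stable, and removes any global rigid motion);
  `align = FALSE` serves pre-aligned trajectories, where planted
  per-residue fluctuations are recovered exactly.
* Welch's test with two all-tied samples has no t distribution;
  equality of means yields p = 1, otherwise p = 0.
* All stochastic stages take explicit seeds and restore the caller's
  RNG state; oracle outputs are pure functions of (request, seed).

## Problem sizes in the shipped examples and tests

The shipped demonstrations are sized for a single CPU: 30-residue
monomer designs with a 2 000-evaluation budget and a fitness threshold
of 1.8 (reached within ~700 evaluations), 25 redesigns per backbone
with the top 5 benchmarked, 10-seed convergence studies on a length-8,
4-letter toy landscape whose optimum is known exhaustively, 10 000
draws for sampler-calibration checks, and 50-screen simulation studies
for the colony statistics. All sizes scale up by changing the
corresponding arguments; nothing in the implementation is specific to
these sizes.

## Known limitations

The synthetic oracle's limitations are listed above and are the main
caveat: quantitative success rates against real predictors are out of
reach without the predictors themselves. Beyond that: the evolutionary
loop implements one member of the greedy-with-exploration family
(fitness-band eligibility, point mutation, elitism) — other published
variants (recombination, rank bands) are configuration or small
extensions; `tm_score` is not a TMalign replacement (no alignment
search); mmCIF is read but not written; and the codon optimiser's
hairpin model is a perfect-stem scan, not a thermodynamic folding
prediction.
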