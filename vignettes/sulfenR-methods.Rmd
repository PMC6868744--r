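---
title: "Methods: how sulfenR predicts S-sulphenylation sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how sulfenR predicts S-sulphenylation sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The prediction problem

S-sulphenylation oxidizes a cysteine thiol to a sulfenic acid
(Cys-SOH). Whether a given cysteine is susceptible depends on its local
sequence environment (flanking charge and hydrophobicity, notably
enrichment of Leu/Lys/Glu/Asp and depletion of Cys/Ser/Phe around
modified sites) and on its structural context (disorder, solvent
exposure). sulfenR therefore treats each cysteine as a 21-residue
window — ten residues either side of the central `C` — and predicts a
probability that the site is modified.

Two modelling assumptions follow from this framing. First, a fixed,
symmetric window is informative enough; cysteines closer than ten
residues to a terminus are kept by padding with the neutral residue
`X`, so every cysteine in a proteome is predictable (the alternative,
dropping terminal sites, silently loses candidates). Second, the
structural tracks are *predicted* quantities (DISOPRED, PSIPRED,
NetSurfP, PSI-BLAST profiles), not crystallographic truth; the model
consumes them as numeric features and is agnostic about their origin,
which is also what makes the deterministic mock provider a valid
stand-in for testing.

## Feature encodings

Nine blocks are computed per motif; for the default 21-mer:

* **AAC** (20): occurrence counts of the 20 amino acids divided by the
  window length 21. `X` contributes to no dimension, so the vector sums
  to `(21 - #X) / 21`.
* **CKSAAP** (2400): for each spacing `k = 0..5` and ordered pair
  `(a, b)`, the count of `a ... b` with exactly `k` residues in between
  divided by the number of k-spaced slots, `W - k - 1` with `W = 21`.
  Pairs touching an `X` are dropped from the numerator only — the
  denominator stays `W - k - 1`, so heavily padded windows shrink
  towards zero rather than being renormalized into false confidence.
* **BLOSUM62** (441): each position contributes its residue's 21-entry
  row of the standard NCBI BLOSUM62 matrix (20 substitution scores plus
  the terminal-signal `*` column). Padded positions use the matrix's
  `X` row.
* **PSSM** (441 / 420 / 400, see below): per-position PSI-BLAST
  log-odds rows, zero rows at padded positions.
* **AAindex** (1344): 64 physicochemical indices x 21 positions; an `X`
  position scores the mean of the index over the 20 amino acids.
* **BINARY** (441): one-hot over the alphabet `A..Y, X` per position.
* **DISOPRED** (20): disorder scores of the 10 upstream and 10
  downstream residues; the central cysteine is excluded because it is
  constant by construction.
* **PSIPRED** (84): per position, the predicted class coded
  `C = 0, E = 1, H = 2` plus the three class probabilities.
* **ACC** (147): seven NetSurfP scores per position. Their natural
  ranges differ by orders of magnitude (a 0/1 burial flag next to
  absolute accessibilities in Å²), so each score type is min-max
  rescaled with constants fitted on the training data; at prediction
  time new values are clipped into [0, 1]. Padded positions are zero
  *after* rescaling — "no residue" must stay a neutral value, not
  inherit whatever raw zero rescales to.

### The PSSM width knob

Published dimensionalities for profile blocks are inconsistent across
descriptions of this encoding family: a 21 x 21 layout (20 log-odds
plus the per-position information content) gives 441 columns, while a
20-score, 20-position layout gives 400 and makes the nine blocks total
5297. Rather than privileging one arithmetic silently, the width is a
configuration knob: `encoder_config(pssm_width = 21)` (default, 441),
`pssm_width = 20` (420), and `pssm_width = 20, pssm_drop_terminal =
TRUE` (400, the configuration under which the block dimensions sum to
5297). The dropped position is the last window slot.

### The AAindex list

The AAindex database holds hundreds of indices; which 64 to use is a
genuine choice. sulfenR ships a documented default — eight indices in
each of eight property clusters (hydrophobicity, polarity/charge, helix
propensity, strand/turn propensity, volume, flexibility, accessibility,
transfer energy), drawn from the AAindex1 release distributed with
seqinr — and accepts any other accession list via
`encoder_config(aaindex_ids = ...)`. Selection results name features by
accession, so they stay portable across configurations.

## Feature selection

With ~5300 features and hundreds of training motifs, most columns are
noise. Selection is two-phase:

1. **mRMR ranking.** Every feature is discretized by supervised MDL
   binning (Fayyad–Irani: recursive entropy-minimizing cuts, accepted
   only when the information gain exceeds the minimum-description-
   length cost; features with no accepted cut collapse to one bin and
   carry zero mutual information). Ranking is greedy with the MID
   criterion `I(f; y) - mean_{s in S} I(f; s)`, plug-in estimates in
   nats. MID rather than the quotient form because it is the classic
   default and numerically stable when redundancy terms approach zero.
   Ties break by column order, which makes runs reproducible.
2. **Forward incremental selection.** Candidates are tried in rank
   order; one is kept only if it does not decrease either the
   random-forest or the SVM cross-validated AUC and strictly increases
   at least one. "Improves both models" is the strictest reading that
   still lets a feature help one learner while being neutral for the
   other. The walk stops after `patience` (default 20) consecutive
   rejections — the AUC curve has passed its peak — so the full ranking
   never needs scanning. The inner CV is 5-fold by default, cheaper
   than the 10-fold used at the model level, because it runs once per
   candidate.

`rf_permutation_importance()` implements the raw out-of-bag form of
permutation importance: per tree, the out-of-bag correct-classification
count minus the same count after permuting one feature, divided by the
out-of-bag size, averaged over trees. A feature the forest never splits
on scores exactly zero (the difference is identically zero tree by
tree), which the tests assert.

## The two-stage ensemble

Stage 1 trains, per feature set (nine blocks + the selected subset,
ten sets, 20 models):

* a **random forest** with balanced class weights. The tree count is
  the rounded square root of the feature count, floored at 100: the
  square-root rule gives absurdly small forests for the 20-column
  blocks (sqrt(20) ≈ 4 trees), so the floor is the default and the
  literal rule is available via `stack_config(literal_trees = TRUE)`.
* an **SVM** whose kernel (linear, polynomial, RBF) is chosen by
  out-of-fold cross-validated AUC. Features are standardized inside the
  wrapper; probabilities come from Platt scaling — a logistic fit of
  the training labels on the decision values — which is deterministic
  and avoids a second nested cross-validation.

Stage 2 is a feed-forward network with 20 inputs (the base models'
probabilities), one hidden unit and one output, logistic activations,
bias terms in the hidden and output layers, L2 weight decay 0.1,
trained by BFGS from a seeded initialization. A 3 x 3 grid search
(units {1, 3, 5} x decay {0, 4e-4, 0.1}) is available via
`meta_grid_search()` for users who want to re-tune.

The meta network is trained on **out-of-fold** stage-1 probabilities.
This is the one place stacking implementations commonly go wrong:
feeding in-sample base-model scores to the meta-learner lets it read
memorized labels and produces spectacular but meaningless internal CV
numbers. The test suite contains an explicit leakage check: on
label-shuffled data the out-of-fold stacking inputs score near chance
at the meta level, while the in-sample scores of the same forests score
near 1 — exactly the gap the out-of-fold design removes. At prediction
time, base models refit on the full training set are used.

All randomness — fold assignment, forests, network initialization —
derives from one seed recorded in the model object, and prediction is a
deterministic function of (model, input).

## The synthetic generator

`generate_dataset()` emulates the statistical structure the method
assumes: negatives draw flank residues i.i.d. from a background
distribution (uniform by default; the human-proteome background is
deliberately out of scope), positives from the background tilted by a
per-residue log-odds shift, default +2 nats for L/K/E/D and −2 for
C/S/F at every flank position — a strong version of the enrichment
pattern observed around real sites. Structural tracks are drawn
class-conditionally: positive motifs' disorder and relative-
accessibility means are shifted by `structural_effect` (default 0.5).
Pseudo-PSSM rows score the motif's own residue highly plus integer
noise, so the PSSM block carries class signal only through sequence
composition.

What the generator does **not** emulate: positional heterogeneity
(real enrichment varies with distance from the cysteine), residue
autocorrelation along the flank, homology between motifs, realistic
class imbalance (real negatives outnumber positives ~8:1), or
informative structure in the PSIPRED track. Passing the end-to-end
tests therefore demonstrates that the machinery recovers planted
signal and does not hallucinate signal under the null — not that any
particular accuracy will be reached on proteome data.

`position_enrichment_table()` is the generator's validator: per
position and residue, `log((f_pos + 0.5/n_pos) / (f_neg + 0.5/n_neg))`.
The central row is reported `NA` (every motif has `C` there, the ratio
is degenerate by construction).

## Numerical conventions and degenerate inputs

* AUC is the Mann–Whitney rank statistic with average ranks, i.e. ties
  count one half; it equals the trapezoidal ROC area and is checked
  against an all-pairs oracle in the tests.
* MCC with a zero denominator is reported as 0, with a message.
* Min-max rescaling of a constant score column maps to 0, with a
  warning at fit time.
* Sequences with no cysteine yield an empty motif set, not an error;
  single-class inputs to AUC or to the enrichment table are errors.
* Non-standard residues (U, B, Z, J, O, `*`) map to `X` on FASTA read,
  with a warning, keeping the encoder alphabet closed at 21 letters.
* MDL discretization of a constant feature returns a single bin
  without error; an all-constant feature matrix is an error for mRMR.
* Stratified folds are dealt round-robin within each class after a
  seeded shuffle, so every fold's class ratio is within one sample of
  the global ratio.

## Problem sizes used in the simulation studies

The heavy end-to-end runs (tests and `scripts/acceptance.R`) use
n = 500 + 500 training motifs, 150 + 150 held-out motifs, 3-fold
stacking CV, 3-fold selection CV, mRMR ranking of the top 60 features
and patience 20. These sizes were chosen so a study completes in
minutes on one CPU while leaving the conclusions unchanged; the
package defaults for real use remain 10-fold model-level CV, 5-fold
selection CV and an mRMR depth of 100.

## Known limitations

* Parsers target specific external-tool dialects (PSI-BLAST 2.2.x
  ASCII PSSM, DISOPRED3 `.diso`, PSIPRED 3.x `.ss2`, NetSurfP-1.1
  tabular) and fail loudly with a dialect hint on anything else;
  NetSurfP-2/3 and AlphaFold-derived features are out of scope.
* Homology reduction of motif sets (e.g. clustering at 30% identity)
  is expected to happen upstream; the package does not deduplicate
  related motifs, and cross-validation on homology-laden data will be
  optimistic.
* The model is trained per run; there is no shipped pre-trained
  human-proteome model.
* SVM training is quadratic in the number of motifs; beyond a few
  thousand motifs per class the stage-1 fits dominate runtime.
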