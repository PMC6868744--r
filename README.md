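# sulfenR

Prediction of protein **S-sulphenylation** sites from sequence.

S-sulphenylation is the reversible oxidation of a cysteine thiol
(Cys–SH) to a sulfenic acid (Cys–SOH). It acts as a fast redox switch in
signalling and enzyme regulation, but the modification is unstable and
hard to catch experimentally, so computational screening of candidate
cysteines is a standard first step. sulfenR is aimed at
bioinformaticians who want a self-contained, scriptable predictor: it
works from 21-residue sequence windows centred on each cysteine and
needs no external services (outputs of PSI-BLAST, DISOPRED, PSIPRED and
NetSurfP can be supplied when available; a deterministic mock provider
and a synthetic-data generator stand in otherwise).

## The model

Each candidate site is a 21-mer motif `s(-10) ... s(-1) C s(+1) ... s(+10)`
(termini padded with `X`). Nine feature blocks are computed per motif:

| block | features | content |
|---|---|---|
| AAC | 20 | amino-acid composition, counts / 21 |
| CKSAAP | 2400 | k-spaced pair composition, `N_i / (W - k - 1)`, k = 0..5 |
| BLOSUM62 | 441 | per-position substitution profile (20 aa + terminal signal) |
| PSSM | 400* | per-position PSI-BLAST log-odds profile |
| AAindex | 1344 | 64 physicochemical indices x 21 positions |
| BINARY | 441 | per-position one-hot over the 21-letter alphabet |
| DISOPRED | 20 | predicted disorder of the 20 flanking residues |
| PSIPRED | 84 | predicted secondary-structure class + 3 probabilities |
| ACC | 147 | 7 surface-accessibility scores, min-max rescaled to [0, 1] |

(*) the PSSM width is configurable: 441 columns with the per-position
information score, 400 in the compatibility layout that makes the nine
blocks total 5297 features.

Features are ranked by **mRMR** (mutual information on MDL-discretized
copies, MID criterion `I(f;y) - mean_s I(f;s)`) and a subset is chosen
by **forward incremental selection**: a candidate is kept only if it
does not decrease either the random-forest or the SVM cross-validated
AUC and strictly improves at least one.

The classifier is a **two-stage stacked ensemble**: for each of the ten
feature sets (nine blocks + the selected subset), a balanced
random forest and a kernel-selected, Platt-calibrated SVM are trained;
their out-of-fold positive-class probabilities feed a single-hidden-unit
feed-forward neural network (logistic activations, weight decay 0.1)
whose output is the final probability. Out-of-fold stacking is used so
the meta-learner never sees in-sample base-model scores.

## Worked example

```r
library(sulfenR)

# a labelled synthetic study: enriched L/K/E/D, depleted C/S/F in positives
train <- generate_dataset(synth_config(n_pos = 200, n_neg = 200, seed = 1))
test  <- generate_dataset(synth_config(n_pos = 60,  n_neg = 60,  seed = 2))

model <- sulfen_train(train$dataset, train$store,
                      n_folds = 3, inner_folds = 3,
                      n_rank = 40, patience = 10, seed = 1)
pred <- predict_stacked(model, test$dataset, test$store)
head(pred, 3)
#>   protein_id position              sequence probability    label
#> 1  SYNP00001       11 KNLEIIETDLCLKYKDPWKDE   0.9904054 positive
#> 2  SYNP00002       11 LDTEDDEDAECEEMPDLTKLE   0.9903724 positive
#> 3  SYNP00003       11 WKEEAVWDDMCEELIKMVWLN   0.9899822 positive

metrics_from_scores(test$dataset$label, pred$probability)
#> TP 60  TN 60  FP 0  FN 0
#> sensitivity 1.000  specificity 1.000  accuracy 1.000  MCC 1.000  AUC 1.000
```

`probability` is the meta-network output in (0, 1); `label` applies the
0.5 cutoff. On this strongly separable synthetic study the model is
essentially perfect; real proteome data is far harder (the flank
composition shift is much weaker and the negatives vastly outnumber the
positives).

A command-line interface wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "sulfenR.R", package = "sulfenR"))')
Rscript $CLI simulate --out sim --n-pos 200 --n-neg 200 --seed 1
Rscript $CLI train    --motifs sim/motifs.tsv --annot-dir sim/annotations \
                      --out model.rds --seed 1
Rscript $CLI predict  --model model.rds --fasta sim/proteins.fasta \
                      --mock --out predictions.tsv
```

Every run writes a `.manifest.json` with the configuration, seed,
package version and input checksums.

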