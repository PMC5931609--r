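# csom — Consensus Self-Organizing Maps for imbalanced multi-class classification

`csom` turns an unsupervised self-organizing map (SOM) into a multi-class
classifier designed for strongly imbalanced data, such as the prediction of
ABC-transporter substrates (P-glycoprotein, MRP1, BCRP — the membrane pumps
behind multidrug resistance in cancer) from molecular descriptors, where a
handful of substrates per transporter sit among a thousand non-substrates.
It is written for cheminformaticians and machine-learning practitioners who
need class predictions with an explicit "don't know" output and metrics that
are not swamped by the majority class.

## The method

A SOM projects high-dimensional feature vectors onto a two-dimensional
lattice of neurons by competitive learning; here the lattice is a **torus**
(both axes wrap), so every cell has a full 8-cell Moore neighbourhood and no
boundary artefacts. Labelled training data occupies only part of the map.
Three ingredients turn the map into a classifier:

1. **Probability expansion.** Each occupied cell gets the mean class
   distribution of its examples, frozen thereafter. Empty cells are filled
   wavefront-wise: at each wave, every empty cell adjacent to previously
   filled cells receives their contribution-weighted probability vectors
   (occupied sources weighted by example count, expanded sources by 1),
   normalized so each cell's vector *p(c | cell)* sums to 1. The wavefront
   fills the whole torus, yielding a complete classifier surface.
2. **Consensus priors.** Because training starts from random weights,
   *P* maps are trained from consecutive seeds; for each training example
   the class labels of its cell-and-Moore-ring neighbours are tallied per
   run, normalized, and averaged over runs. The resulting per-example
   distribution — soft where an example keeps landing on class boundaries —
   replaces its hard label inside the expansion. Around *P* ≈ 10 the
   averaged distributions stabilize.
3. **Threshold gating.** A query is assigned the class of its best-matching
   unit only if max *p* strictly exceeds a threshold *t*; otherwise it is
   returned as the explicit token `non-conclusive` and reported separately
   (`pct_out`) instead of polluting the confusion matrix.

Around this core the package provides SMOTE oversampling and random
undersampling, imbalance-aware metrics (mean and geometric-mean recall,
macro F, percent non-conclusive), stratified k-fold cross-validation with
k-NN baselines in feature space and on the map, descriptor-preparation
operators (|r| > 0.9 correlation pruning, sigmoid scaling, an SVD linear
autoencoder), readers for delimited and KEEL `.dat` tables, and a seeded
generator of imbalanced Gaussian class structures (ratios up to 1:93).

## Worked example

```r
library(csom)
d <- sim_overlap3(seed = 1)          # 30 + 30 + 300 examples, 3 classes
fit <- csom(d$x, d$labels, P = 10, threshold = 0.5,
            config = som_config(20, 20, rounds = 30, radius_start = 10, seed = 1))
holdout <- sim_overlap3(seed = 2)
pred <- predict(fit, holdout$x)
table(pred)
classification_metrics(prediction_tally(holdout$labels, pred))
```

prints

```
pred
             A              B              C non-conclusive
            19             21            313              7
accuracy 0.935 | mean recall 0.750 | G-mean recall 0.732 | F 0.805 | % out 1.9
```

Two ten-fold minority classes (A, B) overlap a ten-times-larger majority
(C). Of 360 held-out points, 7 (1.9 %) fall in ambiguous map regions and are
withheld rather than guessed; the remaining predictions reach a mean
per-class recall of 0.75 — the metric to watch under imbalance, since
accuracy (0.935) is dominated by the majority class. `predict(fit, x,
type = "prob")` returns the full probability vectors, `plot(fit)` draws the
class regions of the torus, and `write_csom()` / `read_csom()` persist the
model as JSON.

A shell interface with the same defaults as the ABC-transporter experiment
(100 × 100 grid, initial radius 20, *t* = 0.9, *P* = 10) is installed at
`inst/scripts/csom-cli` (subcommands `fit`, `predict`, `evaluate`,
`simulate`, `label`).

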