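---
title: "Consensus self-organizing maps: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus self-organizing maps: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csom)
```

## The model

`csom` classifies by geometry rather than by a discriminative loss. An
online self-organizing map projects feature vectors onto a toroidal lattice
of neurons; a wavefront "probability expansion" then assigns every lattice
cell a class-probability vector from the labelled training examples mapped
onto it; prediction reads the vector at a query's best-matching unit (BMU)
and withholds the answer when no class clears a confidence threshold. The
approach is attractive for imbalanced problems because no class ever
competes for model capacity: minority examples claim their own map
territory, and ambiguous territory is reported as such.

### SOM training

Features are standardized per column (z-score) before training; the scaler
is stored on the fitted object and reapplied to all later queries, which
makes BMU assignments invariant to per-feature affine rescaling of the
inputs. Weights initialize i.i.d. uniform on $[0,1)$ from the seeded RNG.
Training is the classical online rule over `rounds` epochs; within each
epoch the examples are presented in a fresh seeded permutation. For epoch
$e \in \{0, \dots, E-1\}$:

* learning rate $\alpha(e) = \alpha_0 (\alpha_1/\alpha_0)^{e/(E-1)}$
  (geometric interpolation between the configured endpoints, chosen because
  it reproduces both endpoints exactly and is the standard SOM schedule);
* adaptation radius $r(e)$ interpolated linearly from `radius_start` to
  `radius_end` (default 1), in grid units;
* every neuron within torus distance $r(e)$ of the BMU moves by
  $w \leftarrow w + \alpha h (x - w)$ with the Gaussian kernel
  $h = \exp(-d^2 / (2 (r/2)^2))$, i.e. the configured radius is treated as
  a $2\sigma$ cut-off.

The default initial learning rate is 2.0. Values above 1 make the raw
update overshoot, so $\alpha$ is clamped at 1.0 *inside* the update (the
configured value is kept verbatim in the config and in serialized models);
with the default schedule the clamp is active for roughly the first third
of training and the effective rate then decays geometrically to 0.01. BMU
ties are broken toward the lexicographically smallest `(row, col)` — they
are measure-zero events in practice but make every test deterministic.
Coordinates are 0-based `(row, col)` throughout; cells are stored row-major.

`rounds = 0` is legal and returns the initialized map, which is how the
package measures quantization error "before training" in its own tests.

### Probability expansion

Occupied cells receive the example-count-weighted mean of their examples'
class distributions; these vectors are frozen and act as sources. Filling
proceeds in synchronous waves: a still-empty cell joins wave $k$ when at
least one of its 8 Moore neighbours was filled before wave $k$, and its
vector is the normalized sum of $w_s \cdot p_s$ over those neighbours,
where $w_s$ is the example count for occupied sources and 1 for expanded
sources. Three design points were genuinely open and are resolved as
follows:

* **Connectivity is 8 (Moore), not 4.** Diagonal transfer keeps the
  expansion isotropic on the torus and matches the neighbourhood used for
  the consensus tally.
* **Iteration to a full fill.** One transfer pass cannot fill a large map
  from sparse occupancy (a 100×100 grid holds $10^4$ cells but only on the
  order of $10^3$ are occupied), so expansion repeats until every cell is
  filled; the torus is connected, so termination is guaranteed.
* **Second-generation weights are 1.** Cells filled by expansion pass on
  their (already averaged) vector with unit weight; re-using example counts
  would double-count dense cells at increasing range.

The implementation is vectorized over the 8 wrap-around shift permutations
of the cell vector; the test suite checks it cell-by-cell against an
independent brute-force fixed-point implementation on random
configurations, along with normalization, frozen-occupied, and
translation-equivariance properties.

### Consensus priors

$P$ maps are trained with seeds `base_seed … base_seed + P − 1`. In each
run, for each example, the labels of all *other* examples in its BMU cell
or the surrounding Moore ring are tallied; a run in which an example has no
neighbours contributes the example's own label (so rows always normalize).
Per-run tallies are normalized and averaged. The fitted classifier then
trains one further map with seed `base_seed + P` — a fresh run rather than
one of the consensus runs, so the prior estimate and the final geometry are
independent — and each example contributes its prior row instead of a
one-hot vector during expansion. When priors are exactly one-hot this
reduces to expansion on raw labels, which the tests assert; the reduction
is the reason this operationalization of "priors" was chosen over
alternatives that would rescale expansion weights. Occupied cells are
averages of prior rows, so priors do modulate the frozen vectors as well.

The default $P = 10$ reflects where the averaged distributions stop moving:
on the package's 300-example, 3-class benchmark the median per-example
max-absolute difference between $P=10$ and $P=30$ tables is well below 0.1
(about 0.003 in the acceptance run).

### Threshold gating and multi-label data

A prediction is conclusive iff $\max_c p(c) > t$ — strictly, so $t = 1$
withholds everything and $t = 0$ withholds nothing (every probability
vector has a positive maximum). Non-conclusive predictions are an explicit
factor level / CSV token, never `NA`. The count of withheld predictions is
non-decreasing in $t$ by construction, which the tests sweep.

Examples carrying several labels (e.g. a compound transported by two
pumps) contribute a uniform distribution over their labels in both the
consensus tally and the expansion. In confusion tallies a conclusive
prediction on a multi-label truth is credited when it matches any true
label, otherwise charged to the first. This is deliberately minimal: the
motivating dataset contains only two dual substrates, too few to fit a
dedicated multi-label mechanism.

## Imbalance machinery

* **SMOTE** synthesizes minority points as $x + u(x' - x)$, $u \sim U(0,1)$,
  with $x'$ one of the $k = 5$ nearest same-class neighbours ($k$ is the
  technique's conventional default and is capped at class size − 1).
  Synthetic rows are flagged, which the cross-validation tests use to prove
  no synthetic point ever reaches a test fold.
* **Metrics** are computed over conclusive predictions only; withheld
  examples surface as `pct_out`. Mean recall — the arithmetic mean of
  per-class recalls — is the headline metric because recall is insensitive
  to class sizes; the geometric mean is also reported, with zero recalls
  floored at $10^{-12}$ and flagged rather than silently collapsing the
  product. The multi-class F measure is the macro-average of per-class F1
  (harmonic mean of precision and recall, 0 when both are 0), consistent
  with the macro treatment of recall. Recall and precision of an absent
  class are 0.
* **Resampling inside CV** is fitted on the training portion of each fold
  only. This is the leakage-free choice; published figures obtained with
  resampling applied before splitting would look slightly better than a
  leakage-free re-run, so comparisons across protocols should keep this in
  mind.
* **Cross-validation** is stratified (per-class shuffled round-robin, fold
  sizes within a class differing by at most one); classes smaller than the
  fold count are spread round-robin with a warning rather than erroring,
  since 1:93 regimes make such classes unavoidable. The paired $t$-test
  between methods compares fold-wise mean-recall series (fold-level
  pairing); identical series return $t = 0, p = 1$, while any other
  zero-variance difference is reported as a degenerate result with `NA`
  statistics rather than a fabricated $p$-value.

## Descriptor preparation

Correlation pruning scans columns left to right and drops a column whose
$|r|$ with any kept column exceeds 0.9 — absolute correlation, because an
anti-correlated descriptor carries the same information; keeping the
earlier column makes the operation order-stable and idempotent. Sigmoid
scaling maps each feature through $1/(1+e^{-(x-\mu)/\sigma})$ with the
column mean and standard deviation (slope = sample SD; zero-variance
columns fall back to $\sigma = 1$ with a warning); parameters are fitted on
training data and reusable on test data. The auto-associative reduction is
the closed-form linear autoencoder: center, take the top-$n$ right singular
vectors (default $n = 10$), encode by projection — the SVD solution is the
Frobenius-optimal rank-$n$ reconstruction, so no iterative network training
is needed or used.

## The synthetic generator

`generate_imbalanced()` draws each class from a seeded diagonal-covariance
Gaussian; `sim_overlap3()` fixes the package's standard benchmark — two
minority classes and a 10× majority at the corners of an equilateral
triangle of side 3 with unit spread, i.e. class centres 3 SD apart, which
puts a few percent of each class inside its neighbours' territory. This
emulates what matters for the method — multi-class structure, partial
boundary overlap, severe imbalance (up to 1:93 in the generator's range) —
and deliberately not what doesn't: real descriptor tables are
higher-dimensional, non-Gaussian, with correlated features and a
structurally heterogeneous majority class. Passing tests on the generator
therefore demonstrate the algorithmic properties (correct expansion,
converging priors, honest gating, the CSOM-over-k-NN ordering under
imbalance), not chemical-domain accuracy. `sim_correlation_table()` is a
synthetic stand-in for a curated screening table: it reproduces prescribed
per-class substrate counts under the −0.3 calling rule but contains no real
measurements.

## Problem sizes and numerical choices

The tests and the acceptance analysis run at desk scale, chosen so the full
suite completes in a couple of minutes while every property remains
informative: expansion is cross-checked on 100 random 6×6 configurations
(exhaustive metric checks on 4×4), consensus convergence on 300 examples
with 12×12 maps, and the cross-validated CSOM vs SOM+k-NN comparison on the
360-example 1:1:10 benchmark with 20×20 maps, 30 rounds, radius 10→1,
$P = 10$, $t = 0.5$, SMOTE in-fold, over 10 data seeds. Probability vectors
are validated to sum to 1 within $10^{-9}$; the expansion oracle agreement
is required below $10^{-12}$. All randomness flows from explicit integer
seeds; per-fold model seeds are spaced by $P + 1$ so no SOM run shares a
seed with another.

## Known limitations

* Rectangular toroidal lattices only — no hexagonal or planar topology, no
  batch-SOM training.
* The probability surface is not calibrated; threshold $t$ trades coverage
  against precision but $p$ values should not be read as calibrated
  posteriors.
* Transfer weights in the expansion are uniform per source; no
  distance-decayed kernels.
* Multi-label support is the minimal uniform-split convention described
  above.
* k-NN baselines use exact distances and scale quadratically with training
  size; they are baselines, not production classifiers.
* With the default learning rate the first epochs move weights by full
  replacement ($\alpha$ clamped at 1), so very small maps can thrash early;
  the decaying schedule recovers, but users wanting classical dynamics can
  simply set `lr_start < 1`.
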