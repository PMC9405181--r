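---
title: "Swarm-optimised canonically correlated sparse autoencoders for EEG seizure classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Swarm-optimised canonically correlated sparse autoencoders for EEG seizure classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seizecca)
```

## The problem and the data layout

Epileptic seizures show up in scalp EEG as characteristic high-amplitude
activity; distinguishing ictal (during-seizure) segments from interictal and
other non-seizure states is the core task of automated seizure screening.
`seizecca` works on tabular segment data in the layout of the UCI epileptic
seizure recognition dataset: one row per one-second EEG segment, 178 numeric
columns (the 178 Hz samples of that second, treated as features), and one
integer class column. Two labelings are supported: binary (class 0 =
seizure, class 1 = everything else, a 1:4 imbalance in the reference data)
and five-class (seizure, tumour region, healthy region, eyes closed, eyes
open), with the seizure class at 0.

The pipeline has four stages:

1. **Min-max normalization** per feature, `(x - x_min)/(x_max - x_min)`.
2. **Wrapper feature selection** by the coyote optimization algorithm (COA).
3. **Classification** by a deep canonically correlated sparse autoencoder
   (DCSAE).
4. Optional **hyperparameter tuning** of the classifier by the krill herd
   algorithm (KHA).

Evaluation uses stratified k-fold cross-validation (default 10-fold) with
sensitivity, specificity, precision, accuracy, F-score, Matthews correlation
and one-vs-rest ROC/AUC.

## Normalization without leakage

`fit_minmax()` records per-feature extremes; `apply_minmax()` maps the
fitted range onto [0, 1]. Two deliberate choices: constant columns map to 0
(keeping the transform total), and held-out values outside the fitted range
are *not* clipped, preserving the linearity of the map. Inside
cross-validation the parameters are re-fitted on every training fold —
`kfold_evaluate()` deliberately takes a whole `fit` callback so that
normalization and feature selection cannot see held-out rows.

## Feature selection: coyote optimization as a wrapper

COA is a population metaheuristic organised in packs. Positions are
initialised uniformly inside the box (`init_population()`); each sweep a
coyote moves under the influence of its pack's alpha (best member) and the
pack's *cultural tendency* (`social_tendency()`, the componentwise median,
read as the mean of the two middle ranked values for even pack sizes), and
keeps the move only if the cost strictly improves. Packs also produce a pup
(`birth_pup()`) that mixes two parents' genes — two dimensions are always
inherited, one from each parent — with scatter probability `Prs = 1/D` of a
fresh random gene and association probability `Pra = (1 - Prs)/2`; the pup
replaces the worst pack member when strictly better. Candidate moves are
clipped to the bounds (boundary handling is otherwise unspecified for this
family of methods). There is no inter-pack exchange; `n_packs` stays in the
configuration so one could be added later.

For feature selection the search runs over `[0, 1]^D` and every position is
binarised at 0.5 before evaluating

```
fitness = alpha * error(mask) + (1 - alpha) * |mask| / D,    alpha = 0.99
```

so classification error dominates and subset size breaks near-ties. The
error estimator is pluggable; the default is the stratified 3-fold CV error
of a regularised linear discriminant classifier (ridge on the pooled
within-class covariance, class priors from training frequencies — closed
form, deterministic, cheap enough for thousands of wrapper evaluations; the
deep classifier itself would be prohibitive inside the loop, and
least-squares-on-indicator alternatives mask middle classes when class
means are collinear, exactly the geometry of ordered mean shifts). An all-false mask is assigned error 1 without calling the estimator.
Fitness values are cached per mask because the continuous search revisits
masks constantly.

One consequence of the parsimony term worth understanding: when the class
signal is extremely strong, a *subset* of the informative features already
achieves near-zero estimated error, and the size term then correctly prunes
the redundant informative features. Recovery of a full planted set is
therefore only the optimum of this objective when each planted feature
carries non-redundant signal at the given sample size — which is how the
recovery benchmark below is constructed.

## The classifier

Deep CCA learns two nonlinear maps `f`, `g` of two data views so that the
canonical correlation of `f(X)` and `g(Y)` is maximal:

```
max  (1/N) tr(U' f(X)' g(Y) V)
s.t. U'((1/N) f(X)'f(X) + r_x I) U = I,   V'((1/N) g(Y)'g(Y) + r_y I) V = I
```

(views centred, rows = samples). `cca_layer()` solves this by whitened SVD:
the correlation is the sum of the top-L singular values of
`S11^{-1/2} S12 S22^{-1/2}`, and `U`, `V` are the whitened singular
directions. Eigenvalues are clamped at 1e-12 and the ridge terms default to
`r_x = r_y = 1e-4`. The DCSAE adds sparse-autoencoder terms to this
objective: mirrored decoders reconstruct each view (`lambda/N` weighted
squared error) and every sigmoid encoder layer pays a Bernoulli KL penalty
`KL(rho || rho_hat)` pulling its batch-mean activations toward a sparsity
target (default 0.05), with mean activations clamped to
`[1e-6, 1 - 1e-6]` so the penalty stays finite.

**What are the two views for EEG?** The source method never says. The
default here is supervised: view X is the (selected, normalized) feature
vector and view Y is the one-hot class indicator, so maximising canonical
correlation drives the projection `U'f(x)` toward directions that separate
the classes — consistent with using the model as a classifier. A `"split"`
mode (feature vector halved into two views) is available for unsupervised
representation learning and for the linear-reduction checks.

**Activations.** The reference settings name ReLU, but the KL sparsity
penalty needs activations in (0, 1); hidden layers therefore use the
logistic sigmoid, and decoder outputs are linear. `activation = "linear"`
turns the encoders into linear maps, under which the correlation term
reduces exactly to classical CCA — the basis of an oracle test against
`stats::cancor()`.

**Training.** All gradients are computed analytically — the correlation
gradient via the singular-triplet form of the DCCA derivative, the rest by
standard backpropagation — and are verified against central finite
differences in the test suite. Per epoch, reconstruction and sparsity terms
take minibatch steps (`batch_size`, default 64, with dropout 0.5 on encoder
hidden activations in that stream), and after every minibatch the
correlation term takes one step whose covariances are always estimated on
the *full* training set: small-batch covariance estimates of the CCA
objective are rank-deficient, while per-epoch-only full-batch steps converge
too slowly at desk scale. Updates use gradient descent at learning rate 0.01
with classical momentum 0.9 (set `momentum = 0` for plain descent, as the
monotone-descent test does). Dropout is excluded from the correlation stream
and from the logged per-epoch loss components so the training log reflects
the actual objective. A non-finite loss aborts with the failing epoch.

**Prediction.** After training, `U`, `V` are recomputed from the clean
encoder outputs, and each class receives a centroid in canonical space.
A new segment is projected as `U'(f(x) - mean)` and assigned the nearest
centroid (Euclidean; ties to the lower class index — relevant only on
measure-zero events but documented for reproducibility). Negated distances
serve as per-class scores for ROC analysis. The number of canonical
directions defaults to `min(10, 2 * n_classes, encoder widths, view width)`;
with a one-hot label view only `n_classes - 1` directions carry signal and
the remainder are benign noise directions whose centroids nearly coincide.

## Hyperparameter tuning: the krill herd

KHA moves each candidate ("krill") by three summed motions: (i) induced
motion from neighbours within a sensing distance (mean pairwise distance /
5) plus attraction to the best krill with gain `2 (rand + I/I_max)`, scaled
by the maximal induced speed 0.01 and an inertia weight decaying linearly
0.9 to 0.1; (ii) foraging toward the inverse-fitness-weighted food centroid
(gain `2 (1 - I/I_max)`) and toward the incumbent best, at foraging speed
0.02 with the same inertia schedule; (iii) random diffusion of magnitude
0.005 decaying linearly to exactly zero at the final iteration. Positions
advance by `dt = 0.5 * 0.5 * sum(upper - lower)` times the summed motions
and are clipped to the bounds. Fitness differences are normalised by
`(K_worst - K_best)` and directions by distances, each with epsilon 1e-10.
The foraging and diffusion internals are only *named* in the source method;
the standard krill-herd forms above are used, with every constant exposed in
`kha_config()`. No genetic operators are attached.

For tuning, krill live in the unit hypercube and decode through a
`hyperparam_space()` (log or linear scales, integers rounded half-up). The
fitness of a decoded configuration is the percent validation error
(`error_rate_fitness()`, misclassified/total x 100) after a reduced
training budget (default 10 epochs) on a stratified internal split; the
winner should be retrained at the full budget. Two robustness choices: a
krill whose training diverges scores the worst possible 100 and the swarm
continues; and the swarm is warm-started with the encoding of the base
configuration, so the tuned configuration can never score worse than the
default on the same split. Inside `run_pipeline()` tuning (off by default —
it multiplies training cost) runs once on the full table with its own
internal split rather than once per CV fold; this trades a small optimistic
bias in fold metrics for a k-fold reduction in cost, and is flagged here
deliberately.

## Metrics

All metrics derive from the confusion matrix (rows = actual). Multiclass
tables are summarised one-vs-rest per class and macro-averaged (unweighted —
the reference tables report an unqualified "average"); MCC is likewise
per-class one-vs-rest rather than the single multi-category coefficient,
matching the table layout. Zero-denominator metrics return 0 and are named
in a `flags` attribute rather than erroring or silently inflating scores.
ROC curves sweep thresholds over distinct scores with ties grouped, so the
trapezoid AUC equals the normalised Mann-Whitney U statistic exactly (an
oracle test asserts this identity). Folds are stratified with a fixed seed.

## The synthetic generator: what it does and does not emulate

`simulate_eeg_segments()` reproduces the *layout and difficulty structure*
of the reference data: 178 features, 2-5 classes, optional 1:4 imbalance,
and planted class-informative columns where class c is shifted by
`c * class_separation` noise SDs. A `sinusoid-segment` mode generates rows
that are one-second sinusoids at class-specific frequencies for
waveform-flavoured smoke tests. It does **not** emulate EEG physiology — no
1/f spectra, no spike-wave morphology, no channel correlations — so passing
benchmarks demonstrate that the pipeline recovers planted statistical
structure, not that it meets any clinical performance bar.

Benchmark regimes used by the tests, fixed once:

* **Classification benchmarks** use `class_separation = 3` ("high SNR"):
  the Bayes error is well under 1%, so pooled CV accuracy >= 0.90 probes the
  machinery, not the task difficulty.
* **The planted-recovery benchmark** (5 informative of 30 features, n = 600)
  uses `class_separation = 1.5`: each planted feature then carries
  non-redundant signal, making the full planted set the optimum of the
  parsimony-penalised wrapper objective. At separation 3 the wrapper
  (correctly) keeps only 3-4 of the 5 redundant planted features.
* **Optimizer sanity benchmarks** minimise the 5-D sphere on `[-1, 1]^5`
  (centred unit-scale box with an interior optimum, matching the unit boxes
  both optimizers search in this package).
* The acceptance studies run at 1500 segments x 178 features (binary
  300/1200, multiclass 5 x 300), 10-fold CV, selection with 3 packs x 6
  coyotes x 30 iterations, 50 training epochs — sizes at which a laptop run
  finishes in minutes.

## Numerical choices, degenerate inputs, limitations

* Covariances use `1/N`; ridge terms keep them invertible; eigenvalues are
  clamped at 1e-12 before inverse square roots.
* `cca_layer()` refuses `N <= L`; training refuses fewer rows than canonical
  dimensions; single-class tables are rejected by selection, training and
  tuning with typed errors (`seizecca_error_*` classes map to CLI exit codes
  2/3/4).
* Constant feature columns normalise to 0; empty feature masks are assigned
  worst error; uniform swarms/packs degenerate gracefully (zero tendencies,
  zero motions).
* Determinism: every stage derives its seed from one master seed; identical
  configurations reproduce artifacts byte-for-byte (stage timings in the
  manifest are the only exception).
* Known limitations: the label-view DCSAE is a discriminative projection
  method, so its advantage over a plain linear classifier shows only when
  class structure is nonlinear in the features; with very few samples per
  feature the canonical directions overfit (visible as a train/test gap),
  and feature selection or more data is needed; linear-activation mode with
  momentum and large learning rates can diverge (reported with the failing
  epoch).
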