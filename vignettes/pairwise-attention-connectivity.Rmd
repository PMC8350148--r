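---
title: "Pairwise-attention connectivity networks: model, training and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pairwise-attention connectivity networks: model, training and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panfc)
```

## The problem

Longitudinal trauma cohorts ask a prognostic question: given a single fMRI
session acquired shortly after the event, can we predict who will meet
diagnostic criteria for PTSD at later follow-ups, which DSM-5 symptoms they
will endorse, and whose early diagnosis will persist? `panfc` implements an
end-to-end neural network for this setting. Its input is one parcellated
scan per subject — an `N x T` matrix of regional BOLD time courses (the
Harvard-Oxford parcellation used in this line of work has `N = 117` regions;
a 10-minute resting scan at TR = 2 s gives `T = 300` samples) — and its
outputs are multi-label clinical predictions read from a *learned*
functional-connectivity matrix.

## The model

Six stages, applied per subject:

1. **Region embedding.** A shared feature extractor `E` maps each region's
   series `s_i` to an embedding `e_i = E(s_i)` of dimension `d` (default
   32). `E` is six 1-D convolutions (64/128/256/256/512/512 filters, kernel
   3, padding 1, ReLU), max-pooling (kernel 2, stride 2) after layers 1, 2,
   4 and 6, and a final linear map. Four halvings imply `T >= 16`.
2. **Pairwise connectivity.** A similarity network `F` — three linear
   layers ending in a sigmoid — scores every ordered pair:
   `k_ij = F([e_i, e_j])`, giving the matrix `K` with entries in (0, 1).
3. **Attention.** Each region aggregates its outgoing scores:
   `w_i = beta + (1 - beta) * sum_{j != i} k_ij`, with `beta = 0.9` by
   default. The sum is implemented exactly as a sum (not a mean), so
   `w_i` ranges over `[beta, beta + (1 - beta)(N - 1)]`; `beta = 1`
   disables attention.
4. **Reweighting.** Updated embeddings `e'_i = w_i * e_i`.
5. **Updated connectivity.** The *same* network `F` scores the reweighted
   embeddings: `k'_ij = F([w_i e_i, w_j e_j])`, giving `K'`.
6. **Classification.** A classifier `C` (linear 100 → linear 32 → linear
   `l`, ReLU + dropout after the first two) reads `K'` flattened row-major,
   diagonal included, and emits `l` logits: `l = 3` for diagnosis at the
   three follow-ups, `l = 20` for the DSM-5 symptoms, `l = 1` for the
   persistence (survival) task. The probability threshold is 0.5.

`F` is not symmetrised: `K` and `K'` are asymmetric in general, and the
diagonal is computed (the classifier reads a dense flatten) but excluded
from the attention sums. Downstream edge statistics symmetrise with
`(k'_ij + k'_ji) / 2` and drop the diagonal. The hidden widths of `F`
(64, 16) and the classifier's second width (32) are package defaults — the
reference architecture fixes only the 100-wide first
classifier layer — as is the dropout rate 0.5. All are `panfc_config()`
arguments.

## Training objective

Both connectivity matrices are supervised with the same classifier:
`L1` is the masked, class-weighted binary cross-entropy of `C(flatten(K))`,
`L2` the same for `K'`, and the objective is
`L = lambda * L1 + (1 - lambda) * L2` with `lambda = 0.6` by default.
Inference always reads `K'` (with `lambda = 1` the second matrix still
exists; it is simply untrained through its own loss term). Each head
coordinate is an independent binary problem; the positive-class weight is
the observed negative/positive ratio on the training subjects (a 72%
positive rate gives weight 28/72), so positive and negative mass balance.
Labels lost to follow-up are `NA` and contribute nothing to loss or
gradient — masking, never imputation; the loss averages over observed
entries only. The severity variant replaces the cross-entropy with a masked
MSE against severity scores z-scored on the training split (the scaler is
stored in the fitted object and predictions are returned on the original
scale).

The optimizer is Adam; the package defaults reproduce the reference
protocol (`beta1 = 0.5`, `beta2 = 0.999`, learning rate 1e-4 divided by 10
every 30 epochs — we read "decreased by 10" as division — 100 epochs, batch
size 20, final short batch kept, epoch shuffling seeded). Evaluation uses
repeated random 80/20 subject-level splits (default 5), reporting mean and
SD of accuracy, rank AUC (ties count one half), average precision and
balanced accuracy per head; `sensitivity_sweep()` re-runs the whole
cross-validation over a grid of `beta` or `lambda`.

## The synthetic cohort generator

No clinical data ship with the package; `simulate_cohort()` generates
cohorts with exactly the statistical structure the model and the edge
statistics assume, and every claim the test suite makes is made on such
cohorts.

* **Signals.** Every region is a stationary AR(1) series (default
  coefficient 0.3, roughly the lag-1 autocorrelation of resting BOLD at
  TR = 2 s). For *chronic* cases each planted region pair additionally
  shares its own latent AR(1) signal injected into both members with gain
  `g` (`effect_strength`), so the planted-pair correlation is
  `g^2 / (1 + g^2)` while all marginal distributions are unchanged — after
  the default per-series z-scoring the group signal lives purely in
  pairwise coupling, which is what the architecture claims to detect. An
  optional amplitude confound and a raw-scale switch exist for studying
  shortcuts.
* **Trajectories.** Each subject is control, remit-early, remit-late or
  chronic with probabilities `(1 - p1, p1 - p2, p2 - p3, p3)`, so the
  marginal prevalences match the configured values (defaults
  72% / 29% / 23%) and diagnosis is monotone non-increasing. The chronic
  indicator drives both the planted coupling and a latent severity, so the
  persistence label has learnable signal.
* **Symptoms and severity.** Diagnosed subjects draw 20 symptom bits that
  always satisfy the four DSM-5 cluster minima (B >= 1 of 5, C >= 1 of 2,
  D >= 2 of 7, E >= 2 of 6; drawn at rate 0.7 and repaired upward where a
  cluster falls short); non-diagnosed subjects carry sub-threshold noise
  (rate 0.15). Severity is a linear function of diagnosis and chronicity
  plus Gaussian noise.
* **Dropout.** Loss to follow-up is monotone (lost at t2 implies lost at
  t3); defaults mirror the emulated cohort design (25/160 then 5/135). All entries of a
  dropped time-point are `NA`.

What the generator does *not* emulate: hemodynamic response and task
structure, spatial autocorrelation between parcels, scanner drift and
motion artefacts, site effects, and — most importantly — any marginal
(amplitude or spectral) group differences, which real patient data likely
contain. Passing tests therefore demonstrate that the implementation
recovers pure pairwise-coupling signal under its own assumptions, not that
the model attains any particular accuracy on clinical data.

## Numerical choices

Several choices matter in practice and are worth recording.

* **Similarity-oriented initialisation** (`similarity_init`, default on).
  With plain fan-in uniform initialisation the first layer of `F` is an
  arbitrary linear map of `[e_i, e_j]`; at small weight scales `F` is
  locally linear, and a linear function of a pair whose *marginals* are
  group-identical has a group-identical mean — coupling is invisible to
  first-order statistics, and in our experiments gradient descent then
  either memorises subjects or collapses `K` to a constant. The default
  initialisation instead makes every first-layer unit a projection of
  `e_i - e_j` (weight blocks `[w, -w]`) and pools them with nonnegative
  second-layer weights, so the initial score is a monotone function of the
  pair's embedding distance — a genuine similarity measure whose mean
  responds to coupling from the first step. Training is free to reshape it.
* **Calibrated classifier initialisation** (`calibrated_init`, default
  on). Sigmoid connectivity scores concentrate near 0.5 with a spread of
  order 0.01–0.1; a classifier reading 400+ nearly constant inputs learns
  extremely slowly and whole ReLU layers can die in unison. At
  initialisation the training-set mean and spread of the flattened
  connectivity are folded into the first layer's weights and biases —
  exactly equivalent to standardising the classifier input, expressed as a
  data-dependent choice of initial parameters (the LSUV idea). The model
  class is unchanged.
* **Initialisation gains** (`init_gain_E`, `init_gain_F`). Six
  fan-in-initialised layers shrink unit-variance inputs to embeddings of
  magnitude ~0.1, too small for the ReLU nonlinearity of `F` to act. The
  desk-scale studies use gains 1.9 (compounding across the seven `E`
  layers) and 2, which bring embeddings to order 1.
* **Optimizer extensions** (`panfc_control`): per-module learning-rate
  scales, decoupled weight decay (AdamW), and multi-restart warm-up
  selection — several short seeded warm-ups, continuing the one with the
  lowest *training* loss, the `kmeans` `nstart` idiom. All default to the
  plain reference protocol.
* **Desk-scale training regime.** At the problem sizes used in the tests
  (200 subjects), end-to-end updates of `E` and `F` degraded held-out
  performance at every learning rate tried: the similarity-initialised
  upstream already exposes the coupling, and gradient updates to it mostly
  add memorisation capacity. The validation studies therefore keep `E` and
  `F` at their similarity-oriented random initialisation (`lr_scale_E =
  lr_scale_F = 0`, a random-feature regime) and optimise the classifier
  with a flat learning rate 1e-3, momentum `beta1 = 0.9`, weight decay
  0.1–0.3 and 3–5 restarts. These are choices for this data regime, not new
  defaults; with `panfc_control()` defaults the full end-to-end protocol
  runs unchanged.
* **Ties and degeneracies.** Max-pooling ties resolve to the earlier
  position; zero-variance series correlate as 0 in the Pearson ablation;
  zero-variance edges get `t = 0`, `p = 1` with a warning; a head with no
  observed positives gets class weight 1 with a warning; single-class heads
  report `NA` AUC rather than an error; training aborts with a diagnostic
  on a non-finite loss.

## Problem sizes used in the validation studies

The packaged studies run at a deliberate desk scale: a strong-coupling
cohort (`n = 200`, `N = 20` regions, `T = 120` samples, eight disjoint
planted pairs at gain 3, i.e. within-pair correlation 0.9 for chronic
cases; equal prevalences 0.5 so the three follow-up labels coincide with
the coupled group) for the classification, ablation and edge-recovery
checks; a remitting cohort with realistic prevalences and dropout for
the survival head; and twenty effect-free cohorts (`n = 120`, `N = 15`)
for false-discovery control. The reduced extractor (8/8/16/16/16/16
filters, `d = 32`) keeps the reference layout at a width appropriate to
`N = 20`. Five-fold cross-validation at these sizes reaches held-out AUC
above 0.95 per time-point, survival AUC above 0.9, and places most planted
pairs in the top ten FDR-adjusted edges.

## DSM-5 clusters, dominance and the feature map

`symptoms_to_clusters()` applies the cluster minima; the mapping is
monotone (adding a symptom never unmeets a cluster). `dominant_cluster()`
scores each cluster as the fraction of its symptoms met, converts scores to
mid-rank percentiles within the cohort (ties handled deterministically),
and assigns the top cluster only when it strictly exceeds the runner-up by
a configurable margin (default 0, i.e. a strict unique maximum — the
"if relevant" of the dominance computation is under-specified, so the
strictest reading is the default and the choice is visible in the output).
Subjects without a dominant cluster are skipped in the visualisation.
`extract_hidden_features()` returns the classifier's 100-dimensional first
layer activation, and `embed_2d()` embeds it with an exact O(n^2) t-SNE
(perplexity-calibrated Gaussian affinities, Student-t outputs, momentum and
early exaggeration) — appropriate at cohort sizes of a few hundred.
Identical feature rows are deduplicated before the optimisation and share
one output point, and the default initialisation is the first two principal
components, so duplicates stay exactly coincident.

## Edge statistics

`collect_edges()` evaluates the fitted model per subject and extracts the
symmetrised upper triangle of `K'`; `edge_ttests()` compares each pair
between diagnosed and non-diagnosed subjects (pooled-variance t by default
— the plain independent-samples reading — Welch optional), adjusts across
all `N(N-1)/2` pairs with Benjamini-Hochberg, and reports index, region
names, mean difference, `t`, `df`, raw and adjusted `p`, sorted by adjusted
`p`. Tests pool all subjects by default (a per-split flag is a matter of
passing a subset). Which time-point's diagnosis defines the groups is the
caller's choice, mirroring the per-time-point analyses.

## Known limitations

* The generator's independence assumptions (no spatial smoothness, no
  marginal group differences) make it a *validation* instrument, not a
  simulator of realistic BOLD data.
* End-to-end gradient updates of the extractor and similarity network are
  fully implemented and finite-difference verified, but at a few hundred
  subjects they underperform the frozen similarity-initialised upstream;
  with cohorts an order of magnitude larger this balance may reverse.
* The exact t-SNE is quadratic in cohort size; beyond a few thousand
  subjects a tree-based approximation would be needed.
* The survival head treats persistence as a binary outcome at the last
  follow-up; no censoring model is attempted.
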