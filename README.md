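# panfc — pairwise-attention networks for functional connectivity

`panfc` predicts longitudinal psychiatric outcomes from a single session of
parcellated fMRI. It is aimed at researchers studying post-traumatic stress
after acute trauma, where the clinical questions are prognostic: will this
person meet diagnostic criteria at one, six and fourteen months? which
DSM-5 symptoms will they endorse? will an early diagnosis persist?

## The model

The input for subject *i* is a matrix of regional time courses
`x_i = (s_1, …, s_N)`, one row per atlas region. The network has six
stages:

1. a shared 1-D convolutional extractor `E` embeds each region,
   `e_i = E(s_i) ∈ R^d`;
2. a similarity network `F` (three linear layers + sigmoid) scores every
   ordered pair, `k_ij = F([e_i, e_j])`, forming a learned functional
   connectivity matrix `K ∈ (0,1)^{N×N}`;
3. pairwise attention aggregates each region's outgoing scores,
   `w_i = β + (1 − β) Σ_{j≠i} k_ij`;
4. embeddings are reweighted, `e'_i = w_i e_i`;
5. the same `F` scores the reweighted pairs, `k'_ij = F([w_i e_i, w_j e_j])`,
   giving the updated matrix `K'`;
6. a classifier `C` reads the flattened `K'` and emits `l` logits —
   `l = 3` (diagnosis at three follow-ups), `l = 20` (DSM-5 symptoms) or
   `l = 1` (persistence).

Training minimises `L = λ·L1 + (1 − λ)·L2`, where `L1`/`L2` are masked,
class-weighted binary cross-entropies of the classifier applied to `K` and
`K'` (λ = 0.6, β = 0.9 by default); labels lost to follow-up are masked,
never imputed. Edge-wise two-sample t-tests with Benjamini–Hochberg
correction then identify region pairs whose learned connectivity
discriminates diagnosed from non-diagnosed subjects. Ablations (identity
extractor, Pearson correlation in place of `F`, no reweighting, independent
per-time-point models) are built in, as is a severity-regression variant.

Because clinical fMRI data of this kind are not publicly deposited, the
package ships a synthetic-cohort generator that plants group-dependent
coupling on known region pairs — AR(1) regional signals, a shared latent
signal injected into each planted pair for chronic cases, DSM-5-consistent
symptom vectors, monotone remission trajectories and longitudinal dropout —
so every claim can be validated against ground truth. See the vignette
(`vignettes/pairwise-attention-connectivity.Rmd`) for the full model
account, the generator's assumptions, and the numerical choices.

## Worked example

Simulate a remitting cohort with three planted region pairs, cross-validate
the diagnosis model, and test which edges discriminate:

```r
library(panfc)

cohort <- simulate_cohort(cohort_config(
  n_subjects = 120, n_regions = 12, n_timepoints_signal = 96,
  prevalence_t1 = 0.6, prevalence_t2 = 0.45, prevalence_t3 = 0.35,
  planted_pairs = rbind(c(1, 2), c(3, 4), c(5, 6)),
  effect_strength = 3, seed = 7))

config  <- panfc_config(n_regions = 12, n_timepoints = 96, embed_dim = 16,
                        conv_filters = c(8, 8, 16, 16, 16, 16),
                        f_hidden = c(32, 8), dropout = 0,
                        init_gain_E = 1.9, init_gain_F = 2)
control <- panfc_control(epochs = 40, learning_rate = 1e-3, adam_beta1 = 0.9,
                         weight_decay = 0.1, lr_decay_every = 1000,
                         n_restarts = 3, lr_scale_E = 0, lr_scale_F = 0,
                         seed = 1)

panfc_cv(cohort, head = "dx", config = config, control = control,
         n_splits = 3, seed = 2)
#> Cross-validated evaluation (head 'dx', 3 splits)
#>   head accuracy_mean accuracy_sd ... auc_mean auc_sd ...
#>  dx_t1         0.611      0.0636        0.607 0.0627
#>  dx_t2         0.605      0.0326        0.607 0.0787
#>  dx_t3         0.721      0.0634        0.730 0.1226
```

The scan is acquired once, and only *chronic* cases carry the planted
coupling, so the third follow-up — whose label coincides with chronicity —
is predicted best, while the first follow-up is diluted by transient cases
whose scans look like controls. The edge statistics, by contrast, recover
the planted pairs exactly:

```r
fit    <- panfc_fit(cohort, head = "dx", config = config, control = control)
report <- edge_ttests(collect_edges(fit, cohort),
                      cohort$dataset$labels$dx_t1)
head(report[, c("name_i", "name_j", "mean_diff", "t", "p_adj", "significant")], 5)
#>          name_i     name_j  mean_diff        t        p_adj significant
#> e5_6 region_005 region_006 0.02220417 5.680198 6.498410e-06        TRUE
#> e1_2 region_001 region_002 0.02146485 3.714642 1.030686e-02        TRUE
#> e3_4 region_003 region_004 0.01604036 3.530726 1.302484e-02        TRUE
#> e1_7 region_001 region_007 0.01146306 2.394506 2.501587e-01       FALSE
#> e2_7 region_002 region_007 0.01242237 2.379259 2.501587e-01       FALSE
```

The three planted pairs are the three significant edges at FDR 0.05; every
other pair is rejected. Persistent-label cohorts (equal prevalences, so all
positives are chronic) give held-out AUC above 0.95 at every time-point —
these runs are part of the test suite. The survival head (`head =
"survival"`) and the symptom head (`head = "symptoms"`, with
`symptoms_to_clusters()`, `dominant_cluster()` and `embed_2d()` for the
cluster analyses) follow the same pattern.

A command-line driver covering simulate/train/evaluate/sweep/clusters/edges
is installed at `system.file("cli/panfc.R", package = "panfc")`.

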