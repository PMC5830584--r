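---
title: "cortcat: methods, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cortcat: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models implemented in `cortcat`,
the assumptions behind them, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the design
decisions that were genuinely open. It states no empirical result that the
test suite or the acceptance script does not itself compute.

## 1. The analysis chain

`cortcat` models each fMRI voxel as a linear readout of a hierarchical
stimulus-feature representation, and then uses the fitted models
generatively:

1. **Feature preparation** (`hrf_kernel()`, `prepare_series()`,
   `prepare_train_test()`). Unit activation time series are convolved with
   a canonical hemodynamic response function, averaged within TR windows,
   and standardized. Standardization parameters come from the training
   sessions only and are reused verbatim for test data and static exemplar
   features — `prepare_train_test()` exists precisely so that no test
   statistic can leak into preprocessing (an earlier joint-standardization
   variant was caught by the ablation-additivity test and removed).
2. **Two-stage dimension reduction** (`fit_pca()`,
   `transform_features()`). PCA per layer retaining the smallest number of
   components explaining at least `variance_threshold` (default 0.99) of
   that layer's variance; the layer scores are scaled by `1/sqrt(p_l)`,
   concatenated, and reduced again at the same threshold. The scaling
   gives every layer comparable total energy before the joint reduction,
   so wide layers cannot crowd out narrow ones.
3. **Ridge encoding models** (`fit_ridge()`, `predict()`), minimizing
   `(1/N) * sum_i (r_v(x_i) - f(x_i) w_v)^2 + lambda * ||w_v||^2` via the
   SVD of the design. The penalty is selected by 9-fold cross-validation
   over *contiguous* time blocks (respecting temporal autocorrelation),
   maximizing mean held-out correlation.
4. **Evaluation** (`prediction_accuracy()`, `block_permutation_test()`,
   `noise_ceiling()`, `layer_explained_variance()`).
5. **Category synthesis** (`build_category_atlas()`,
   `category_dprime()`): maps as exemplar-averaged simulated responses;
   d-prime selectivity against the pooled complement.
6. **Similarity, clustering, semantics, layer attribution**
   (`similarity_matrix()`, `signed_modularity()`,
   `cluster_categories()`, `cluster_specific_region()`, `subcluster()`,
   `lch_similarity()`, `representational_semantic_correlation()`,
   `layer_profile()`).

## 2. Key parameters

| parameter | default | units | why |
|---|---|---|---|
| `tr` | 2 | s | sampling interval of the emulated scanner |
| `session_length` | 240 | volumes | 8-minute sessions |
| `n_train_sessions` | 36 | sessions | 4.8 h of training data; desk-scale between the 2.4 h and 12.8 h per-subject training sets this emulates |
| `n_train_repeats` / `n_test_repeats` | 2 / 10 | — | training presented twice, testing ten times |
| HRF `peak_time` | 4 | s | canonical double-gamma kernel, analytic mode exactly at the peak |
| `variance_threshold` | 0.99 | fraction | both PCA stages retain > 99% variance |
| `n_folds` | 9 | — | cross-validation folds for the ridge penalty |
| `block_length` | 20 | s | block-permutation block (10 TRs); the permutation literature does not fix one value |
| `q` / `r` thresholds | 0.01 / 0.2 | — | predictable-voxel mask (strict inequalities) |
| region `alpha` | 0.01 | — | Bonferroni-corrected two-sample t threshold |
| `noise_sd` | 3.2 | signal-SD units | per-repeat noise; puts the 10-repeat-averaged test noise ceiling near 0.7 |

## 3. The hemodynamic kernel

`hrf_kernel()` is a difference of two gamma densities with scale 1: the
response gamma has shape `peak_time + 1`, so its analytic mode is exactly
`peak_time`; the undershoot gamma (shape `3 * peak_time + 1`, amplitude
ratio 1/6) is far enough from the peak that the combined argmax moves by
less than 0.01 s. The kernel starts at exactly zero, is normalized to unit
peak amplitude, and is truncated at 32 s.

## 4. The synthetic world

The generator plants a three-level category hierarchy (superordinate
groups, subgroups, basic-level categories; defaults: biological objects
with terrestrial animals / aquatic animals / plants / humans,
non-biological objects, background scenes with artificial / natural
scenes; 8 subgroups x 4 categories).

**Signatures.** Each category has, per layer, a feature signature
`sqrt(a2) u_G + sqrt(b2) v_g + sqrt(e2) w_c`: a group component, a
subgroup component and a category-unique component. Where the structure
lands is governed by layer bands: the superordinate band peaks near 62% of
the layer depth, the subgroup band grows as `(l/L)^2` towards the top
layer — so coarse structure is a mid-level property and fine structure a
top-level property, which is what the layer-ablation analyses are designed
to recover. Two non-obvious constructions matter:

* group and subgroup directions are **mutually orthogonal by construction**
  (QR of a random frame). With random directions, two superordinate groups
  can be accidentally similar at desk-scale dimensionality
  (overlap ~ 1/sqrt(p)), which makes coarse clustering a coin flip on some
  seeds — an artifact of small `p`, not a property of interest;
* signatures are **centered across categories**. Un-centered signatures
  leave a grand-mean component in the standardized features; every
  synthesized category map then shares the identical "mean stimulus"
  response pattern, a rank-1 common mode that compresses the block
  structure of the similarity matrix. This was diagnosed as the cause of
  unreliable coarse recovery and removed at the source.

**Feature fluctuations.** The non-category activity of each layer is a set
of layer-specific latent AR(1) factors (timescale via
`feature_noise_ar = 0.6` at 1 s steps) mixed through loadings whose factor
variances decay as `exp(-j / feature_spectrum_tau)` (default tau = 2).
Unit activations of trained hierarchical networks are strongly correlated
within a layer, with fast-decaying covariance spectra; this is what makes
a 99%-variance PCA reduction meaningful. A flat (white) spectrum would
leave ~90% of dimensions in the design and make weight recovery at the
stated SNR impossible — the reduction step would be vacuous.

**Voxels.** Each voxel prefers one layer (`concentration = 0.95` of its
squared weight mass); its within-layer tuning is drawn from the span of
the planted category signatures (`signature_tuning = 1`). The dial can be
lowered to mix in tuning aligned with the layer's feature covariance, but
at desk-scale voxel counts that component adds map-space variance that is
unrelated to any category contrast yet correlated across categories
through the sampled voxels; it pushes weak subgroup blocks into the
modularity resolution limit (see section 6) and merges them. With hundreds
of thousands of voxels both choices behave alike; the desk-scale default
is the clean population.

**Responses.** The voxel readout of the features is HRF-convolved,
TR-averaged, scaled to unit signal SD per voxel, and observed under
i.i.d. Gaussian noise per repeat with per-voxel SD
`noise_sd * lognormal(0, 0.1)`. `noise_sd = 3.2` makes the noise ceiling
of the 10-repeat-averaged test data ~ `1/sqrt(1 + 3.2^2/10)` ~ 0.7, the
regime the recovery analyses are calibrated for.

**Exemplars.** Poisson counts around `exemplars_per_category_mean`
(floor 2), or an exact count via `fixed_count` (the full-scale setting of
80 categories x 800 exemplars = 64,000 objects is reachable by config).
Exemplar noise passes through the same loadings as the time-series
fluctuation, so exemplars and movies live in the same feature covariance.

**What a green test does and does not establish.** The generator emulates
session/repeat structure, hemodynamic filtering, layered category
information and realistic feature covariance. It does **not** emulate
spatial voxel correlations (no 3-D volumes or surfaces), stimulus
confounds (luminance, motion energy), non-Gaussian or temporally
autocorrelated measurement noise, categories with overlapping membership,
or a real feature extractor — a planted-recovery pass validates the
statistical machinery, not any claim about a particular brain or network.

## 5. Within/between correlation targets

`within_block_corr = 0.7` and `between_block_corr = 0.25` set the
signature correlation of same-subgroup pairs (at the subgroup-band peak)
and of same-group pairs (at the superordinate-band peak). They were fixed
once, together with the generator parameters above, so that the planted
world actually exhibits the phenomena the pipeline is meant to detect —
coarse clusters recoverable at the whole-"cortex" scale, subgroups
recoverable only at the fine scale — and were frozen before the acceptance
suite was finalized.

## 6. Numerical and statistical choices

* **Signed modularity.** `p_ij = S_ij / S_tot` with `S_tot` the total
  off-diagonal weight over ordered pairs, and
  `q_ij = (rowsum_i/S_tot)(colsum_j/S_tot)` including the `i = j` null
  terms; both sum to one, so a single-cluster partition scores exactly
  zero on each part. Self-similarities (diagonal) carry no edge weight.
  Uniform off-diagonal weights give slightly *negative* Q for every
  partition — a known property of this normalization, asserted in the
  tests. Q-maximization inherits modularity's resolution limit: weak
  blocks whose mutual weight is slightly positive can merge; the planted
  world keeps cross-block similarity near zero so the limit is not
  triggered at the planted scale.
* **k-selection ties** go to the smallest k (parsimony); k-means runs on
  the rows of S (each category's similarity profile) with 50 restarts
  under a fixed seed.
* **Permutation p-values** are always `(1 + #null >= obs) / (1 + n_perm)`,
  never zero. The modularity null shuffles the off-diagonal pair weights
  jointly with their signs, preserving symmetry; the block-permutation
  null permutes contiguous blocks of the predicted series within session
  (circular shifting available by flag).
* **Noise ceiling.** Per session and voxel: noise variance of the
  repeat-averaged series = mean across-repeat variance / R; signal
  variance = variance of the repeat mean minus that, floored at zero;
  Gaussian signal and noise are simulated, the median correlation over
  `n_sim` draws is the session ceiling, averaged across sessions.
* **Fisher z** clips cortical similarities at `|r| = 1 - 1e-7`; the
  semantic side is left untransformed.
* **Zero-variance units/series** are standardized to all-zero columns
  (guarded division) or given r = 0 / d' = 0, always with a flag, never
  dropped — column indexing is preserved.
* **Ridge at lambda = 0** falls back to the pseudo-inverse (SVD truncation
  at the usual numerical-rank tolerance) with a warning.

## 7. Open decisions and the positions taken

* **Ablation order**: layers are zeroed in *standardized* space, so an
  ablated layer contributes exactly zero to the projection and the
  per-layer designs sum to the full design. Zeroing raw features before
  standardization would inject the (negated) training mean instead.
* **Shared vs per-voxel penalty**: one lambda for the population by
  default (`per_voxel = TRUE` available); selection by mean cross-validated
  correlation.
* **Layer-wise Q at a fixed partition**: the per-layer modularity is
  evaluated at the full-model cluster labels, treating the profile as a
  decomposition of one clustered organization; re-clustering per layer is
  possible by calling `cluster_categories()` on a per-layer network.
* **LCH conventions**: node-counted paths (identical labels give p = 1,
  hence `s = log(2d)`), depth in edge levels below the root, natural log;
  an edge-counting flag exists.
* **Cosine "distance"**: computed as cosine *similarity* (higher = more
  similar), consistent with its use alongside LCH.
* **d-prime complement**: pooled over the exemplars of all other
  categories (not over category means), on noiseless model-simulated
  responses.
* **PCA second moments**: both stages center before decomposing; the
  explained-variance threshold applies to centered variance.

## 8. Known limitations

* The ridge solver materializes the full SVD of the design; for designs
  beyond ~10^5 x 10^3 a randomized or blocked solver would be preferable.
* `noise_ceiling()` loops over voxels; it is intended for test-set sizes
  (thousands of voxels), not whole-brain grids.
* The orchestrator's resume logic trusts file existence plus the per-stage
  cache; it does not hash the configuration into the stage key.
* Exemplar counts below 2 are floored (d-prime needs within-category
  variance), which slightly biases the Poisson mean for very small
  `exemplars_per_category_mean`.
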