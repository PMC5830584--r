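# cortcat

Voxel-wise encoding models and the clustered organization of cortical
category representations.

## The problem

How does visual cortex organize information about object categories? One
productive answer treats the cortex as a readout of a hierarchical feature
model: every voxel's response to a natural stimulus is predicted from the
unit activations of a layered (CNN-style) feature hierarchy, and the fitted
models are then used as a "virtual scanner" — simulating the cortical
response map of thousands of category exemplars that were never shown in
the scanner, averaging them into per-category representations, and asking
how those representations cluster, how selective single voxels are, which
feature levels carry the category structure, and how the cortical geometry
relates to the semantic geometry of the category labels.

`cortcat` implements that entire analysis chain for computational
neuroscientists, together with a synthetic-data generator that plants a
known category hierarchy in layered features and voxel populations, so
every stage can be validated against ground truth.

## The model

* **Encoding model.** Layer activations `f_l^o(x)` (length `p_l`) are
  HRF-convolved, downsampled to the TR grid and standardized; each layer is
  reduced by PCA, `f_l(x) = f_l^o(x) B_l`, keeping the smallest `q_l`
  components explaining more than 99% of the layer's variance; the
  `1/sqrt(p_l)`-scaled concatenation across `L` layers is reduced again,
  `f(x) = f_{1:L}(x) B_{1:L}`. Each voxel is a ridge regression
  `r_v(x) = f(x) w_v + e_v`, with the penalty chosen by nine-fold
  cross-validation over contiguous time blocks.
* **Evaluation.** Per-session Pearson correlation between predicted and
  observed test responses, averaged over sessions; block-permutation
  significance with Benjamini-Hochberg FDR; Monte-Carlo noise ceiling from
  test-set repeats (Gaussian signal + noise, median over simulations).
* **Category representations.** A category's cortical map is the average
  model-simulated response over its exemplars. Selectivity is
  `d'_i = (mean_i - mean_ic) / sqrt((var_i + var_ic)/2)` against the pooled
  exemplars of all other categories.
* **Clustering.** The inter-category similarity network (spatial Pearson
  correlations over predictable voxels, `q < 0.01` and `r > 0.2`) is
  clustered by k-means; cluster count maximizes the signed weighted
  modularity `Q = S+/(S+ + S-) Q+ - S-/(S+ + S-) Q-`, with permutation
  significance. Cluster-specific regions (two-sample t-test against random
  objects, Bonferroni) support a second, finer round of clustering.
* **Semantics.** Leacock-Chodorow similarity `s = -log(p / 2d)` on an is-a
  taxonomy, or cosine similarity of label vectors; correlated with the
  Fisher-z cortical similarities over the upper triangle, with
  label-permutation significance.
* **Layer attribution.** Exemplar features are zeroed in all layers but
  one; per-layer category maps decompose the similarity, modularity and
  semantic correlation into feature levels.

## Worked example

A desk-scale end-to-end run on synthetic data with a planted hierarchy
(3 superordinate groups, 8 subgroups, 32 categories):

```r
library(cortcat)
cfg <- pipeline_config(
  generator    = list(n_voxels = 300, units_per_layer = 24,
                      n_train_sessions = 8, n_test_sessions = 2,
                      session_length = 120),
  hierarchy    = list(exemplars_per_category_mean = 12),
  permutations = list(block = 200, modularity = 1000, semantic = 1000),
  seed = 42)
res <- run_pipeline(cfg)
```

which prints (abridged):

```
mean prediction r: 0.592          # test-set accuracy, all voxels
median noise ceiling: 0.681       # the accuracy an exact model could reach
predictable voxels: 299 of 300    # q < 0.01 and r > 0.2
<clustering_result> k = 3, Q = 0.2539 (Q+ = 0.2175, Q- = -0.3587)
modularity permutation p: 0.000999
cortical-semantic r (LCH): 0.663   p: 0.000999
  layer          Q       r_lch
1     1 0.01682007 -0.01077896
2     2 0.03230638  0.10116930
3     3 0.19533954  0.42181730
4     4 0.18195042  0.47848195
5     5 0.16190477  0.49068007
6     6 0.10888328  0.45806534
```

Reading this: the encoding models predict held-out responses at about 87%
of the noise ceiling; the 32 category representations cluster into exactly
the 3 planted superordinate groups with strongly significant modularity;
cortical similarity tracks taxonomy-based semantic similarity; and the
layer-resolved profile peaks in the middle layers (3-4), where the
generator plants the superordinate structure, not in the top layer.

Every stage is also available as plain functions
(`make_layered_features()`, `prepare_train_test()`, `fit_pca()`,
`fit_ridge()`, `build_category_atlas()`, `category_dprime()`,
`cluster_categories()`, `signed_modularity()`, `lch_similarity()`,
`layer_profile()`, ...) — see the package help and the methods vignette
(`vignettes/cortcat-methods.Rmd`).

A command-line wrapper lives at `inst/scripts/cortcat-run.R`:

```sh
Rscript inst/scripts/cortcat-run.R validate --config cfg.json
Rscript inst/scripts/cortcat-run.R run --config cfg.json [--resume]
```

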