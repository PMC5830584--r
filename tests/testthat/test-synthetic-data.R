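test_that("generator_config validates its invariants", {
  expect_s3_class(generator_config(), "generator_config")
  expect_error(generator_config(n_layers = 1), "n_layers")
  expect_error(generator_config(tr = 0), "tr")
  expect_error(generator_config(noise_sd = -1), "noise_sd")
  expect_error(generator_config(n_voxels = 0), "n_voxels")
  expect_error(generator_config(time_step = 0.7), "divide")
  expect_error(category_hierarchy(within_block_corr = 0.1,
                                  between_block_corr = 0.5), ">=")
  expect_error(category_hierarchy(superordinate_groups =
    list(a = c("x", "x"))), "unique")
})

test_that("make_layered_features obeys its shape and determinism contract", {
  cfg <- generator_config(n_layers = 2, units_per_layer = 4, n_voxels = 5,
                          session_length = 25, n_train_sessions = 1,
                          n_test_sessions = 1, seed = 3)
  hier <- category_hierarchy()
  f1 <- make_layered_features(cfg, hier)
  expect_length(f1$layers, 2L)
  for (x in f1$layers) {
    expect_identical(dim(x), c(100L, 4L))  # 2 sessions x 25 TR x 2 steps/TR
    expect_true(all(is.finite(x)))
  }
  f2 <- make_layered_features(cfg, hier)
  expect_identical(f1$layers, f2$layers)
  expect_identical(attr(f1, "scene_category"), attr(f2, "scene_category"))
})

test_that("planted correlation structure lands in the configured layer band", {
  # subgroup structure planted only in layer 2; superordinate only layer 1
  hier <- category_hierarchy(within_block_corr = 0.8, between_block_corr = 0.2,
                             superordinate_band = c(1, 0),
                             subgroup_band = c(0, 1))
  cfg <- generator_config(n_layers = 2, units_per_layer = 40,
                          feature_noise_sd = 0.1, seed = 5)
  sigs <- cortcat:::category_signatures(cfg, hier)
  tab <- hier$table
  same_sub <- outer(tab$subgroup, tab$subgroup, "==") &
    !diag(TRUE, nrow(tab))
  cross_group <- outer(tab$group, tab$group, "!=")
  for (l in 1:2) {
    cm <- cor(t(sigs[[l]]))
    within_l <- mean(cm[same_sub])
    between_l <- mean(cm[cross_group])
    if (l == 2) expect_gt(within_l, between_l + 0.3)
    expect_lt(abs(mean(cm[cross_group])), 0.15)
  }
  # monotonicity: raising within_block_corr raises measured within-block corr
  measured <- sapply(c(0.3, 0.55, 0.8), function(w) {
    h <- category_hierarchy(within_block_corr = w, between_block_corr = 0.2,
                            superordinate_band = c(1, 0), subgroup_band = c(0, 1))
    mean(cor(t(cortcat:::category_signatures(cfg, h)[[2]]))[same_sub])
  })
  expect_true(all(diff(measured) > 0))
})

test_that("voxel population concentrates weight mass on the preferred layer", {
  cfg <- generator_config(n_layers = 3, units_per_layer = 10, n_voxels = 40,
                          concentration = 0.95, seed = 2)
  truth <- make_voxel_population(cfg)
  expect_true(all(truth$preferred_layer %in% 1:3))
  offsets <- c(0L, cumsum(cfg$units_per_layer))
  frac <- sapply(seq_len(40), function(v) {
    blocks <- sapply(1:3, function(l)
      sum(truth$weights[v, (offsets[l] + 1):offsets[l + 1]]^2))
    blocks[truth$preferred_layer[v]] / sum(blocks)
  })
  expect_true(all(frac > 0.9))
  # snr_profile of zeros silences the weights entirely
  cfg0 <- generator_config(n_layers = 3, units_per_layer = 10, n_voxels = 6,
                           snr_profile = 0, seed = 2)
  expect_true(all(make_voxel_population(cfg0)$weights == 0))
})

test_that("simulate_responses has the stated noise structure", {
  cfg <- generator_config(n_layers = 2, units_per_layer = 6, n_voxels = 8,
                          session_length = 50, n_train_sessions = 1,
                          n_test_sessions = 1, n_train_repeats = 2,
                          n_test_repeats = 2, noise_sd = 0, seed = 9)
  hier <- category_hierarchy()
  feats <- make_layered_features(cfg, hier)
  truth <- make_voxel_population(cfg, hier)
  resp <- simulate_responses(feats, truth, cfg)
  # zero noise: repeats identical and equal to the signal
  expect_equal(resp$train$repeats[, , 1], resp$train$repeats[, , 2])
  expect_equal(resp$train$repeats[, , 1], resp$train$signal)

  # zero weights: responses are pure noise with the declared variance
  cfg2 <- generator_config(n_layers = 2, units_per_layer = 6, n_voxels = 4,
                           session_length = 250, n_train_sessions = 2,
                           n_test_sessions = 2, n_train_repeats = 1,
                           n_test_repeats = 2, noise_sd = 1,
                           noise_sd_spread = 0, snr_profile = 0, seed = 10)
  feats2 <- make_layered_features(cfg2, hier)
  truth2 <- make_voxel_population(cfg2, hier)
  resp2 <- simulate_responses(feats2, truth2, cfg2)
  expect_true(all(resp2$train$signal == 0))
  n_samp <- length(resp2$train$repeats[1, , 1])
  for (v in 1:4) {
    s2 <- stats::var(resp2$train$repeats[v, , 1])
    se <- sqrt(2 / (n_samp - 1))  # SE of a unit-variance sample variance
    expect_lt(abs(s2 - 1), 3 * se)
  }

  # mismatched shapes error
  cfg3 <- generator_config(n_layers = 2, units_per_layer = 5, n_voxels = 4,
                           seed = 10)
  truth3 <- make_voxel_population(cfg3, hier)
  expect_error(simulate_responses(feats, truth3, cfg), "units")
})

test_that("response correlation with signal follows the analytic ceiling", {
  # corr(signal, signal + noise) -> sd_s / sqrt(sd_s^2 + sd_n^2)
  hier <- category_hierarchy()
  base <- list(n_layers = 2, units_per_layer = 8, n_voxels = 30,
               session_length = 250, n_train_sessions = 2,
               n_test_sessions = 1, n_train_repeats = 1, n_test_repeats = 1,
               noise_sd_spread = 0, seed = 20)
  obs <- sapply(c(1, 2), function(ns) {
    cfg <- do.call(generator_config, c(base, list(noise_sd = ns)))
    feats <- make_layered_features(cfg, hier)
    truth <- make_voxel_population(cfg, hier)
    resp <- simulate_responses(feats, truth, cfg)
    mean(sapply(seq_len(30), function(v)
      cor(resp$train$repeats[v, , 1], resp$train$signal[v, ])))
  })
  expected <- 1 / sqrt(1 + c(1, 2)^2)  # signal scaled to unit SD
  expect_equal(obs, expected, tolerance = 0.05)
})

test_that("exemplar generation: counts, determinism, degenerate noise", {
  cfg <- generator_config(n_layers = 2, units_per_layer = 4, seed = 4)
  # 80 categories x exactly 800 exemplars = 64,000 objects
  hier80 <- category_hierarchy(categories_per_subgroup = 10,
                               exemplars_per_category_mean = 800)
  ex <- make_category_exemplars(cfg, hier80, fixed_count = 800)
  expect_length(ex$categories, 80L)
  expect_identical(sum(ex$exemplar_counts), 64000L)
  expect_identical(sum(vapply(ex$exemplar_features,
                              function(f) nrow(f$layers[[1]]), integer(1))),
                   64000L)

  # Poisson counts vary but keep the configured mean
  hier <- category_hierarchy(exemplars_per_category_mean = 40)
  exp_counts <- make_category_exemplars(cfg, hier)$exemplar_counts
  expect_gt(stats::sd(exp_counts), 0)
  expect_lt(abs(mean(exp_counts) - 40), 5)

  # zero exemplar noise: all exemplars of a category identical
  cfg0 <- generator_config(n_layers = 2, units_per_layer = 4,
                           exemplar_noise_sd = 0, seed = 4)
  ex0 <- make_category_exemplars(cfg0, hier, fixed_count = 3)
  lay <- ex0$exemplar_features[[1]]$layers[[1]]
  expect_equal(lay[1, ], lay[2, ])

  # same-subgroup signatures correlate more than cross-group ones
  cm <- cor(t(ex$signatures[[2]]))
  tab <- hier80$table
  same_sub <- outer(tab$subgroup, tab$subgroup, "==") & !diag(TRUE, nrow(tab))
  cross <- outer(tab$group, tab$group, "!=")
  expect_gt(mean(cm[same_sub]), mean(cm[cross]))
})

test_that("toy taxonomy mirrors the planted hierarchy", {
  hier <- category_hierarchy()
  tax <- make_toy_taxonomy(hier)
  expect_equal(tax$depth, 3)
  expect_true(all(hier$table$category %in% tax$nodes))
  # same-subgroup categories are closer than cross-group ones
  d <- igraph::distances(tax$graph, mode = "all")
  a <- "terrestrial_animals_01"; b <- "terrestrial_animals_02"
  c1 <- "artificial_scenes_01"
  expect_lt(d[a, b], d[a, c1])
  expect_error(taxonomy(data.frame(child = c("a", "a"), parent = c("r", "r"))),
               "duplicate")
})

test_that("label vectors encode the hierarchy in cosine similarity", {
  hier <- category_hierarchy()
  vec <- make_label_vectors(hier, seed = 8)
  tab <- hier$table
  cs <- function(a, b) vector_cosine(vec, a, b)
  within_sub <- cs("humans_01", "humans_02")
  cross_group <- mean(c(cs("humans_01", "vehicles_01"),
                        cs("humans_01", "natural_scenes_01")))
  expect_gt(within_sub, cross_group)
})
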