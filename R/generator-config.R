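#' Configuration of the synthetic fMRI world
#'
#' Collects every size, timing and noise parameter used by the synthetic-data
#' generators. Defaults mirror the acquisition design the package emulates:
#' TR = 2 s, 8-minute sessions (240 volumes), a training run repeated twice
#' and a testing run of 5 sessions repeated ten times. The default training
#' length (36 sessions, 4.8 h) is a desk-scale compromise between the
#' study-sized per-subject training sets this emulates (2.4 h to 12.8 h).
#'
#' @param n_layers Number of feature layers `L` (>= 2).
#' @param units_per_layer Units per layer `p_l`; recycled to length `n_layers`.
#' @param n_voxels Number of simulated voxels.
#' @param tr Repetition time of the simulated scanner, seconds.
#' @param time_step Sampling step of the raw feature time series, seconds.
#'   Must divide `tr`.
#' @param session_length Volumes (TRs) per session.
#' @param n_train_sessions,n_test_sessions Session counts for the training and
#'   testing runs.
#' @param n_train_repeats,n_test_repeats How often each run is repeated; test
#'   repeats feed the noise-ceiling estimator.
#' @param noise_sd Per-repeat measurement-noise SD, expressed relative to each
#'   voxel's noiseless signal SD (so single-repeat SNR is `1/noise_sd`). The
#'   default 3.2 puts the noise ceiling of the 10-repeat-averaged test data
#'   near 0.7.
#' @param noise_sd_spread SD (log scale) of the lognormal per-voxel multiplier
#'   on `noise_sd`, giving voxels heterogeneous noise levels.
#' @param snr_profile Per-layer multiplicative scale on voxel weights;
#'   recycled to length `n_layers`.
#' @param concentration Fraction of each voxel's squared weight mass placed on
#'   its preferred layer (0, 1].
#' @param signature_tuning Fraction of each voxel's within-layer squared
#'   weight mass aligned with the layer's category-signature subspace (the
#'   rest follows the stimulus feature covariance). Category-selective
#'   cortex is tuned to category-diagnostic feature directions; 0 gives a
#'   population blind to the planted category structure.
#' @param feature_noise_sd Per-unit SD of the feature fluctuation that is not
#'   category-driven.
#' @param feature_noise_ar AR(1) coefficient of that fluctuation (per
#'   `time_step`); values near 0.6 at 1 s keep layer-specific variance inside
#'   the hemodynamic passband.
#' @param feature_spectrum_tau Decay constant of the latent-factor variance
#'   spectrum of the non-category fluctuation (factor j carries variance
#'   proportional to `exp(-j / tau)`). Unit activations of a trained
#'   hierarchical network are strongly correlated within a layer, so the
#'   layer covariance has a fast-decaying eigenspectrum; this is what makes
#'   the 99%-variance PCA reduction meaningful.
#' @param scene_length Duration, seconds, for which one category stays on
#'   screen in the simulated stimulus sequence.
#' @param exemplar_noise_sd Per-unit SD of exemplar-to-exemplar variation
#'   around a category's feature signature.
#' @param seed Master seed; all generators derive their streams from it.
#'
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_layers = 6L,
                             units_per_layer = 48L,
                             n_voxels = 1000L,
                             tr = 2,
                             time_step = 1,
                             session_length = 240L,
                             n_train_sessions = 36L,
                             n_train_repeats = 2L,
                             n_test_sessions = 5L,
                             n_test_repeats = 10L,
                             noise_sd = 3.2,
                             noise_sd_spread = 0.1,
                             snr_profile = 1,
                             concentration = 0.95,
                             signature_tuning = 1,
                             feature_noise_sd = 1,
                             feature_noise_ar = 0.6,
                             feature_spectrum_tau = 2,
                             scene_length = 20,
                             exemplar_noise_sd = 1,
                             seed = 1L) {
  n_layers <- as.integer(n_layers)
  if (!.is_count(n_layers) || n_layers < 2L)
    .stopf("n_layers must be an integer >= 2")
  units_per_layer <- as.integer(rep_len(units_per_layer, n_layers))
  if (any(units_per_layer < 1L)) .stopf("units_per_layer entries must be >= 1")
  counts <- c(n_voxels = n_voxels, session_length = session_length,
              n_train_sessions = n_train_sessions, n_train_repeats = n_train_repeats,
              n_test_sessions = n_test_sessions, n_test_repeats = n_test_repeats)
  for (nm in names(counts)) if (!.is_count(counts[[nm]])) .stopf("%s must be a count >= 1", nm)
  if (!is.finite(tr) || tr <= 0) .stopf("tr must be > 0")
  if (!is.finite(time_step) || time_step <= 0) .stopf("time_step must be > 0")
  if (abs(tr / time_step - round(tr / time_step)) > 1e-8)
    .stopf("time_step must divide tr")
  if (!is.finite(noise_sd) || noise_sd < 0) .stopf("noise_sd must be >= 0")
  if (concentration <= 0 || concentration > 1) .stopf("concentration must be in (0, 1]")
  if (signature_tuning < 0 || signature_tuning > 1)
    .stopf("signature_tuning must be in [0, 1]")
  snr_profile <- rep_len(as.numeric(snr_profile), n_layers)
  if (any(!is.finite(snr_profile)) || any(snr_profile < 0))
    .stopf("snr_profile must be finite and non-negative")
  if (!.is_count(abs(seed) + 1)) .stopf("seed must be an integer")
  structure(list(
    n_layers = n_layers, units_per_layer = units_per_layer,
    n_voxels = as.integer(n_voxels), tr = tr, time_step = time_step,
    session_length = as.integer(session_length),
    n_train_sessions = as.integer(n_train_sessions),
    n_train_repeats = as.integer(n_train_repeats),
    n_test_sessions = as.integer(n_test_sessions),
    n_test_repeats = as.integer(n_test_repeats),
    noise_sd = noise_sd, noise_sd_spread = noise_sd_spread,
    snr_profile = snr_profile, concentration = concentration,
    signature_tuning = signature_tuning,
    feature_noise_sd = feature_noise_sd, feature_noise_ar = feature_noise_ar,
    feature_spectrum_tau = feature_spectrum_tau,
    scene_length = scene_length, exemplar_noise_sd = exemplar_noise_sd,
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' Planted category hierarchy
#'
#' Describes the superordinate groups, their sub-blocks and the basic-level
#' categories of the synthetic stimulus set, together with the target feature
#' correlations that encode the hierarchy into the layered features. Defaults
#' plant three superordinate groups (biological objects, non-biological
#' objects, background scenes) with the biological group split into
#' terrestrial animals, aquatic animals, plants and humans, and the scenes
#' into artificial and natural scenes.
#'
#' @param superordinate_groups Named list: group name -> character vector of
#'   subgroup names. Names must be unique across all levels.
#' @param categories_per_subgroup Basic-level categories per subgroup.
#' @param exemplars_per_category_mean Mean exemplar count per category.
#' @param within_block_corr Target feature-signature correlation between
#'   categories sharing a subgroup, at the layer where the subgroup band
#'   peaks. Must be >= `between_block_corr`.
#' @param between_block_corr Target signature correlation between categories
#'   that share only the superordinate group, at the superordinate band peak.
#' @param superordinate_band,subgroup_band Optional per-layer weights in
#'   \[0, 1\] shaping where in the hierarchy of layers each level of category
#'   structure is injected. `NULL` uses the defaults: superordinate structure
#'   peaking in the middle layers (around 60% depth) and subgroup structure
#'   growing towards the top layer.
#'
#' @return An object of class `category_hierarchy` with a `$table` of
#'   category/subgroup/group assignments.
#' @export
category_hierarchy <- function(superordinate_groups = list(
                                 biological_objects = c("terrestrial_animals",
                                                        "aquatic_animals",
                                                        "plants", "humans"),
                                 nonbiological_objects = c("vehicles", "tools"),
                                 background_scenes = c("artificial_scenes",
                                                       "natural_scenes")),
                               categories_per_subgroup = 4L,
                               exemplars_per_category_mean = 40,
                               within_block_corr = 0.7,
                               between_block_corr = 0.25,
                               superordinate_band = NULL,
                               subgroup_band = NULL) {
  groups <- names(superordinate_groups)
  subgroups <- unlist(superordinate_groups, use.names = FALSE)
  if (is.null(groups) || anyDuplicated(c(groups, subgroups)))
    .stopf("group and subgroup names must be unique and non-empty")
  if (!.is_count(categories_per_subgroup)) .stopf("categories_per_subgroup must be >= 1")
  if (exemplars_per_category_mean < 1) .stopf("exemplars_per_category_mean must be >= 1")
  cc <- c(within_block_corr, between_block_corr)
  if (any(!is.finite(cc)) || any(cc < -1) || any(cc > 1))
    .stopf("correlation levels must lie in [-1, 1]")
  if (within_block_corr < between_block_corr)
    .stopf("within_block_corr must be >= between_block_corr")
  tab <- do.call(rbind, lapply(groups, function(g) {
    do.call(rbind, lapply(superordinate_groups[[g]], function(s) {
      data.frame(category = sprintf("%s_%02d", s, seq_len(categories_per_subgroup)),
                 subgroup = s, group = g, stringsAsFactors = FALSE)
    }))
  }))
  structure(list(
    superordinate_groups = superordinate_groups,
    categories_per_subgroup = as.integer(categories_per_subgroup),
    exemplars_per_category_mean = exemplars_per_category_mean,
    within_block_corr = within_block_corr,
    between_block_corr = between_block_corr,
    superordinate_band = superordinate_band,
    subgroup_band = subgroup_band,
    table = tab
  ), class = "category_hierarchy")
}

# Per-layer band weights in [0, 1] for the two levels of planted structure.
# Superordinate information peaks around 60% of the depth hierarchy;
# subgroup information grows monotonically towards the top layer.
layer_bands <- function(hierarchy, n_layers) {
  sup <- hierarchy$superordinate_band
  sub <- hierarchy$subgroup_band
  if (is.null(sup)) {
    peak <- max(2, round(0.62 * n_layers))
    sup <- exp(-((seq_len(n_layers) - peak) / (n_layers / 4))^2)
  }
  if (is.null(sub)) sub <- (seq_len(n_layers) / n_layers)^2
  sup <- rep_len(sup, n_layers)
  sub <- rep_len(sub, n_layers)
  if (any(sup < 0 | sup > 1) || any(sub < 0 | sub > 1))
    .stopf("band weights must lie in [0, 1]")
  list(superordinate = sup, subgroup = sub,
       superordinate_peak = which.max(sup), subgroup_peak = which.max(sub))
}

# Deterministic per-layer loading matrices of the non-category feature
# fluctuation. Factor j carries variance ~ exp(-j / tau), emulating the
# fast-decaying within-layer covariance spectrum of hierarchical-network
# activations; loadings are normalized so the expected per-unit fluctuation
# variance equals feature_noise_sd^2. Shared by the time-series and
# exemplar generators so both live in the same feature covariance.
layer_noise_loadings <- function(config) {
  withr::with_seed(config$seed + 1511L, {
    lapply(seq_len(config$n_layers), function(l) {
      p <- config$units_per_layer[l]
      s <- exp(-seq_len(p) / (2 * config$feature_spectrum_tau))
      a <- matrix(stats::rnorm(p * p), p, p) %*% diag(s, p)
      a * config$feature_noise_sd / sqrt(sum(s^2))
    })
  })
}

# Deterministic per-layer category feature signatures shared by the
# time-series, exemplar and label-vector generators. For layer l the
# signature of category c decomposes into a group component (variance a2),
# a subgroup component (b2) and a category-unique component (e2), so the
# expected signature correlation is a2 + b2 within a subgroup and a2 across
# subgroups of the same group.
category_signatures <- function(config, hierarchy) {
  tab <- hierarchy$table
  bands <- layer_bands(hierarchy, config$n_layers)
  withr::with_seed(config$seed + 1011L, {
    lapply(seq_len(config$n_layers), function(l) {
      p <- config$units_per_layer[l]
      a2 <- hierarchy$between_block_corr * bands$superordinate[l]
      b2 <- (hierarchy$within_block_corr - hierarchy$between_block_corr) *
        bands$subgroup[l]
      e2 <- max(1 - a2 - b2, 0.05)
      groups <- unique(tab$group)
      subs <- unique(tab$subgroup)
      nG <- length(groups); nS <- length(subs)
      # group and subgroup contrast directions are mutually orthogonal by
      # construction (QR of a random frame), so no pair of superordinate
      # groups is similar by sampling accident; category-unique directions
      # stay random
      base <- matrix(stats::rnorm(p * (nG + nS)), p)
      q <- qr.Q(qr(base))
      n_orth <- min(p, nG + nS)
      frame <- t(q[, seq_len(n_orth), drop = FALSE]) * sqrt(p)
      if (n_orth < nG + nS)
        frame <- rbind(frame, matrix(stats::rnorm((nG + nS - n_orth) * p),
                                     ncol = p))
      gvec <- frame[seq_len(nG), , drop = FALSE]
      svec <- frame[nG + seq_len(nS), , drop = FALSE]
      dimnames(gvec) <- list(groups, NULL)
      dimnames(svec) <- list(subs, NULL)
      cvec <- matrix(stats::rnorm(nrow(tab) * p), ncol = p,
                     dimnames = list(tab$category, NULL))
      sig <- sqrt(a2) * gvec[tab$group, , drop = FALSE] +
        sqrt(b2) * svec[tab$subgroup, , drop = FALSE] +
        sqrt(e2) * cvec
      sig <- sweep(sig, 2L, colMeans(sig))
      rownames(sig) <- tab$category
      sig
    })
  })
}
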