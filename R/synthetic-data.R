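#' Layered feature series container
#'
#' Holds one activation matrix per feature layer, either a time series (rows
#' indexed by sampling times, `time_step` set) or a static set of exemplar
#' rows (`time_step = NULL`).
#'
#' @param layers List of numeric matrices with a common row count.
#' @param time_step Sampling step in seconds, or `NULL` for static exemplars.
#' @param sessions Optional per-row session id (time series only).
#' @param session_role Optional named character vector mapping session id to
#'   `"train"` or `"test"`.
#' @return An object of class `layered_features`.
#' @export
layered_features <- function(layers, time_step = NULL, sessions = NULL,
                             session_role = NULL) {
  if (!length(layers)) .stopf("at least one layer is required")
  layers <- lapply(layers, as.matrix)
  nr <- vapply(layers, nrow, integer(1))
  if (length(unique(nr)) != 1L) .stopf("layers must share a common row count")
  if (any(vapply(layers, ncol, integer(1)) < 1L)) .stopf("each layer needs >= 1 unit")
  if (!is.null(sessions) && length(sessions) != nr[1])
    .stopf("sessions must have one entry per row")
  structure(list(layers = layers, layer_ids = seq_along(layers),
                 time_step = time_step, sessions = sessions,
                 session_role = session_role),
            class = "layered_features")
}

#' @export
print.layered_features <- function(x, ...) {
  kind <- if (is.null(x$time_step)) "static exemplar set" else
    sprintf("time series (step %g s)", x$time_step)
  cat(sprintf("<layered_features> %d layers, %d rows, %s\n",
              length(x$layers), nrow(x$layers[[1]]),
              kind))
  cat("units per layer:", vapply(x$layers, ncol, integer(1)), "\n")
  invisible(x)
}

#' Generate layered feature time series with planted category structure
#'
#' Simulates unit activations of a layered feature hierarchy while a sequence
#' of category "scenes" plays. Each scene presents one basic-level category
#' for `scene_length` seconds; during a scene every layer's activation equals
#' the category's layer signature plus an AR(1) per-unit fluctuation. Where
#' each level of category structure lands is governed by the hierarchy's
#' layer bands: by default superordinate structure is strongest in the middle
#' layers and subgroup structure in the top layers.
#'
#' @param config A [generator_config()].
#' @param hierarchy A [category_hierarchy()].
#' @return A [layered_features()] time series covering
#'   `n_train_sessions + n_test_sessions` sessions, with attributes
#'   `signatures` (per-layer category signature matrices), `scene_category`
#'   (per-row planted category index) and `hierarchy`.
#' @export
make_layered_features <- function(config, hierarchy = category_hierarchy()) {
  if (!inherits(config, "generator_config")) .stopf("config must be a generator_config")
  if (!inherits(hierarchy, "category_hierarchy")) .stopf("hierarchy must be a category_hierarchy")
  sigs <- category_signatures(config, hierarchy)
  n_cat <- nrow(hierarchy$table)
  rows_per_session <- as.integer(round(config$session_length * config$tr / config$time_step))
  n_sessions <- config$n_train_sessions + config$n_test_sessions
  scene_rows <- max(1L, as.integer(round(config$scene_length / config$time_step)))
  withr::with_seed(config$seed + 2011L, {
    scene_cat <- integer(0)
    for (s in seq_len(n_sessions)) {
      n_scenes <- ceiling(rows_per_session / scene_rows)
      cats <- sample.int(n_cat, n_scenes, replace = TRUE)
      scene_cat <- c(scene_cat, rep(cats, each = scene_rows)[seq_len(rows_per_session)])
    }
    sessions <- rep(seq_len(n_sessions), each = rows_per_session)
    phi <- config$feature_noise_ar
    loadings <- layer_noise_loadings(config)
    layers <- lapply(seq_len(config$n_layers), function(l) {
      p <- config$units_per_layer[l]
      x <- sigs[[l]][scene_cat, , drop = FALSE]
      innov_sd <- sqrt(1 - phi^2)
      for (s in seq_len(n_sessions)) {
        idx <- which(sessions == s)
        eps <- matrix(stats::rnorm(length(idx) * p, sd = innov_sd), ncol = p)
        fac <- matrix(stats::filter(eps, phi, method = "recursive"), ncol = p)
        x[idx, ] <- x[idx, ] + fac %*% t(loadings[[l]])
      }
      rownames(x) <- NULL
      x
    })
    role <- stats::setNames(
      rep(c("train", "test"), c(config$n_train_sessions, config$n_test_sessions)),
      seq_len(n_sessions))
    out <- layered_features(layers, time_step = config$time_step,
                            sessions = sessions, session_role = role)
    attr(out, "signatures") <- sigs
    attr(out, "scene_category") <- scene_cat
    attr(out, "hierarchy") <- hierarchy
    out
  })
}

#' Generate a ground-truth voxel population
#'
#' Each voxel reads the layered features linearly. A voxel prefers one layer:
#' a fraction `concentration` of its squared weight mass lies on the units of
#' the preferred layer, the remainder spreads over the other layers. Within a
#' layer the tuning direction is drawn from the layer's feature covariance
#' (the latent-factor loadings), i.e. voxels pool the feature dimensions that
#' natural stimuli actually express rather than arbitrary unit mixtures. The
#' per-layer `snr_profile` scales the weight blocks multiplicatively. Voxels
#' also receive a lognormal noise multiplier so measurement-noise levels vary
#' across the population.
#'
#' @param config A [generator_config()].
#' @param hierarchy The [category_hierarchy()] whose signatures
#'   category-tuned voxels read (must match the one used for the features).
#' @return An object of class `ground_truth_voxels` with fields `weights`
#'   (voxel x total-units matrix), `preferred_layer`, `noise_mult` and
#'   `noise_variance` (relative variance `(noise_sd * mult)^2`, i.e. the
#'   measurement-noise variance per unit of signal variance).
#' @export
make_voxel_population <- function(config, hierarchy = category_hierarchy()) {
  if (!inherits(config, "generator_config")) .stopf("config must be a generator_config")
  L <- config$n_layers
  p <- config$units_per_layer
  offsets <- c(0L, cumsum(p))
  loadings <- layer_noise_loadings(config)
  sigs <- category_signatures(config, hierarchy)
  st <- config$signature_tuning
  withr::with_seed(config$seed + 3011L, {
    pref <- sample.int(L, config$n_voxels, replace = TRUE)
    w <- do.call(cbind, lapply(seq_len(L), function(l) {
      cov_part <- matrix(stats::rnorm(config$n_voxels * p[l]), config$n_voxels) %*%
        t(loadings[[l]])
      sig_part <- matrix(stats::rnorm(config$n_voxels * nrow(sigs[[l]])),
                         config$n_voxels) %*% sigs[[l]]
      cov_part <- cov_part / sqrt(rowSums(cov_part^2))
      sig_part <- sig_part / sqrt(rowSums(sig_part^2))
      sqrt(1 - st) * cov_part + sqrt(st) * sig_part
    }))
    for (v in seq_len(config$n_voxels)) {
      for (l in seq_len(L)) {
        idx <- (offsets[l] + 1L):offsets[l + 1L]
        blk <- w[v, idx]
        nb <- sqrt(sum(blk^2))
        share <- if (l == pref[v]) config$concentration else
          (1 - config$concentration) / max(L - 1L, 1L)
        w[v, idx] <- if (nb > 0) blk / nb * sqrt(share) * config$snr_profile[l] else blk
      }
    }
    mult <- exp(stats::rnorm(config$n_voxels, sd = config$noise_sd_spread))
    structure(list(weights = w, preferred_layer = pref, noise_mult = mult,
                   noise_variance = (config$noise_sd * mult)^2,
                   units_per_layer = p),
              class = "ground_truth_voxels")
  })
}

#' Voxel response container
#'
#' @param values Voxel x time matrix (may be `NULL` when `repeats` is given;
#'   the repeat mean is then used).
#' @param sessions Per-time-point session id (contiguous blocks).
#' @param tr Repetition time, seconds.
#' @param repeats Optional voxel x time x repeat array of raw repeats.
#' @param signal Optional voxel x time noiseless signal (ground truth).
#' @return An object of class `voxel_responses`.
#' @export
voxel_responses <- function(values = NULL, sessions, tr, repeats = NULL,
                            signal = NULL) {
  if (is.null(values)) {
    if (is.null(repeats)) .stopf("either values or repeats must be supplied")
    values <- rowMeans(repeats, dims = 2L)
  }
  values <- as.matrix(values)
  if (length(sessions) != ncol(values))
    .stopf("sessions must have one entry per time point")
  if (any(!is.finite(values))) .stopf("responses must be finite")
  structure(list(values = values, sessions = sessions, tr = tr,
                 repeats = repeats, signal = signal),
            class = "voxel_responses")
}

#' @export
print.voxel_responses <- function(x, ...) {
  cat(sprintf("<voxel_responses> %d voxels x %d time points, %d session(s)%s\n",
              nrow(x$values), ncol(x$values), length(unique(x$sessions)),
              if (is.null(x$repeats)) "" else
                sprintf(", %d repeats", dim(x$repeats)[3])))
  invisible(x)
}

#' Simulate fMRI-like voxel responses from layered features
#'
#' Computes each voxel's linear feature readout, convolves it with the
#' hemodynamic kernel, downsamples to the TR grid (averaging within TR
#' windows), rescales so every voxel's noiseless signal has unit SD, and adds
#' independent Gaussian measurement noise per repeat with per-voxel SD
#' `noise_sd * noise_mult`.
#'
#' @param features A [make_layered_features()] time series covering train and
#'   test sessions.
#' @param truth A [make_voxel_population()].
#' @param config The [generator_config()] used for both.
#' @param hrf Hemodynamic kernel from [hrf_kernel()]; defaults to the
#'   canonical kernel sampled at the feature time step.
#' @return A list with `voxel_responses` elements `train` and `test`, each
#'   carrying the raw `repeats` array and the noiseless `signal`.
#' @export
simulate_responses <- function(features, truth, config,
                               hrf = hrf_kernel(config$time_step)) {
  if (!inherits(features, "layered_features") || is.null(features$time_step))
    .stopf("features must be a layered_features time series")
  if (!inherits(truth, "ground_truth_voxels")) .stopf("truth must be a ground_truth_voxels")
  p_tot <- sum(vapply(features$layers, ncol, integer(1)))
  if (ncol(truth$weights) != p_tot)
    .stopf("weight columns (%d) do not match total units (%d)", ncol(truth$weights), p_tot)
  if (abs(features$time_step - hrf$resolution) > 1e-9)
    .stopf("hrf resolution must equal the feature time step")
  by <- as.integer(round(config$tr / features$time_step))
  x <- do.call(cbind, features$layers)
  sess <- features$sessions
  ids <- unique(sess)
  # convolution and TR-averaging are linear and commute with the voxel
  # readout, so convolve the (few) feature columns, not the voxel signals
  xd_list <- lapply(ids, function(s)
    .downsample_rows(.convolve_cols(x[sess == s, , drop = FALSE], hrf$taps), by))
  signal <- do.call(rbind, xd_list) %*% t(truth$weights)  # TR-grid time x voxel
  tr_sessions <- rep(ids, vapply(xd_list, nrow, integer(1)))
  sd_v <- apply(signal, 2L, stats::sd)
  sd_v[sd_v == 0] <- 1
  signal <- sweep(signal, 2L, sd_v, "/")
  noise_sd_v <- config$noise_sd * truth$noise_mult
  role <- features$session_role
  withr::with_seed(config$seed + 4011L, {
    build <- function(which_role, n_rep) {
      keep <- tr_sessions %in% ids[role[as.character(ids)] == which_role]
      sig <- t(signal[keep, , drop = FALSE])        # voxel x time
      dimnames(sig) <- NULL
      reps <- array(0, dim = c(nrow(sig), ncol(sig), n_rep))
      for (r in seq_len(n_rep))
        reps[, , r] <- sig + matrix(stats::rnorm(length(sig)), nrow = nrow(sig)) * noise_sd_v
      voxel_responses(sessions = tr_sessions[keep], tr = config$tr,
                      repeats = reps, signal = sig)
    }
    list(train = build("train", config$n_train_repeats),
         test = build("test", config$n_test_repeats))
  })
}

#' Average repeats and standardize voxel responses
#'
#' Mirrors the preprocessing applied to measured responses before model
#' fitting: repeats are averaged, then each voxel's series is standardized
#' (zero mean, unit variance) within each session.
#'
#' @param responses A [voxel_responses()] (with or without repeats).
#' @return A `voxel_responses` whose `values` are repeat-averaged and
#'   session-wise standardized; the repeats array is dropped.
#' @export
preprocess_responses <- function(responses) {
  stopifnot(inherits(responses, "voxel_responses"))
  vals <- if (!is.null(responses$repeats))
    rowMeans(responses$repeats, dims = 2L) else responses$values
  for (s in unique(responses$sessions)) {
    idx <- responses$sessions == s
    seg <- vals[, idx, drop = FALSE]
    mu <- rowMeans(seg)
    sdv <- apply(seg, 1L, stats::sd)
    sdv[sdv == 0] <- 1
    vals[, idx] <- (seg - mu) / sdv
  }
  voxel_responses(values = vals, sessions = responses$sessions,
                  tr = responses$tr, signal = responses$signal)
}

#' Generate category exemplar feature sets
#'
#' For every category, draws a set of static layered feature vectors: the
#' category's layer signature plus independent per-unit exemplar noise.
#' Exemplar counts are Poisson around `exemplars_per_category_mean` (with a
#' floor of 2), or exactly `fixed_count` when supplied.
#'
#' @param config A [generator_config()] (fixes layer sizes and signatures).
#' @param hierarchy A [category_hierarchy()].
#' @param fixed_count Optional exact exemplar count per category.
#' @param seed Seed for counts and exemplar noise.
#' @return An object of class `category_exemplars`: list with `categories`,
#'   `exemplar_features` (one static [layered_features()] per category),
#'   `exemplar_counts` and `hierarchy`.
#' @export
make_category_exemplars <- function(config, hierarchy = category_hierarchy(),
                                    fixed_count = NULL,
                                    seed = config$seed + 5011L) {
  if (!inherits(hierarchy, "category_hierarchy") || !nrow(hierarchy$table))
    .stopf("hierarchy must be a non-empty category_hierarchy")
  sigs <- category_signatures(config, hierarchy)
  cats <- hierarchy$table$category
  withr::with_seed(seed, {
    counts <- if (is.null(fixed_count))
      pmax(stats::rpois(length(cats), hierarchy$exemplars_per_category_mean), 2L)
    else rep(as.integer(fixed_count), length(cats))
    names(counts) <- cats
    loadings <- layer_noise_loadings(config)
    noise_gain <- config$exemplar_noise_sd /
      max(config$feature_noise_sd, .Machine$double.eps)
    ex <- lapply(seq_along(cats), function(ci) {
      layers <- lapply(seq_len(config$n_layers), function(l) {
        p <- config$units_per_layer[l]
        noise <- matrix(stats::rnorm(counts[ci] * p), ncol = p) %*%
          t(loadings[[l]]) * noise_gain
        sweep(noise, 2L, sigs[[l]][cats[ci], ], "+")
      })
      layered_features(layers)
    })
    names(ex) <- cats
    structure(list(categories = cats, exemplar_features = ex,
                   exemplar_counts = counts, hierarchy = hierarchy,
                   signatures = sigs),
              class = "category_exemplars")
  })
}

#' Generate random, non-selective object exemplars
#'
#' Each random object gets its own random feature signature (no shared
#' category structure) plus exemplar noise, matching the scale of planted
#' category exemplars. These serve as the null reference when defining
#' cluster-specific cortical regions.
#'
#' @param config A [generator_config()].
#' @param n Number of random objects.
#' @param seed Seed.
#' @return A static [layered_features()] with `n` rows.
#' @export
make_random_exemplars <- function(config, n, seed = config$seed + 6011L) {
  if (!.is_count(n)) .stopf("n must be a count >= 1")
  loadings <- layer_noise_loadings(config)
  noise_gain <- config$exemplar_noise_sd /
    max(config$feature_noise_sd, .Machine$double.eps)
  withr::with_seed(seed, {
    layers <- lapply(seq_len(config$n_layers), function(l) {
      p <- config$units_per_layer[l]
      matrix(stats::rnorm(n * p), ncol = p) +
        matrix(stats::rnorm(n * p), ncol = p) %*% t(loadings[[l]]) * noise_gain
    })
    layered_features(layers)
  })
}

#' Build the toy is-a taxonomy mirroring the planted hierarchy
#'
#' Nodes are root -> superordinate groups -> subgroups -> categories, with
#' directed child-to-parent is-a edges; the default hierarchy has depth 3
#' (edge levels below the root).
#'
#' @param hierarchy A [category_hierarchy()].
#' @param root Name of the root node.
#' @return An object of class `taxonomy`: `nodes`, `edges` (data.frame with
#'   `child`, `parent`), `root` and `depth`.
#' @export
make_toy_taxonomy <- function(hierarchy = category_hierarchy(), root = "entity") {
  tab <- hierarchy$table
  edges <- rbind(
    data.frame(child = names(hierarchy$superordinate_groups), parent = root,
               stringsAsFactors = FALSE),
    data.frame(child = unique(tab$subgroup),
               parent = tab$group[match(unique(tab$subgroup), tab$subgroup)],
               stringsAsFactors = FALSE),
    data.frame(child = tab$category, parent = tab$subgroup,
               stringsAsFactors = FALSE))
  taxonomy(edges, root = root)
}

#' Taxonomy constructor
#'
#' @param edges Data frame with columns `child` and `parent` (is-a pairs).
#' @param root Root node name; inferred as the unique parent that is never a
#'   child when omitted.
#' @return A `taxonomy` object with `depth` = maximum number of edges from
#'   the root to any node.
#' @export
taxonomy <- function(edges, root = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("child", "parent") %in% names(edges))) .stopf("edges need child/parent columns")
  if (anyDuplicated(edges$child)) .stopf("duplicate child labels in taxonomy edges")
  nodes <- unique(c(edges$child, edges$parent))
  if (is.null(root)) {
    cand <- setdiff(edges$parent, edges$child)
    if (length(unique(cand)) != 1L) .stopf("taxonomy must have a single root")
    root <- unique(cand)
  }
  g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                     directed = TRUE, vertices = nodes)
  if (any(is.infinite(igraph::distances(g, to = root, mode = "out"))))
    .stopf("taxonomy must be connected through the root")
  if (!igraph::is_dag(g)) .stopf("taxonomy must be a DAG")
  depth <- max(igraph::distances(g, to = root, mode = "out"))
  structure(list(nodes = nodes, edges = edges, root = root, depth = depth,
                 graph = g),
            class = "taxonomy")
}

#' Generate label vectors reflecting the planted hierarchy
#'
#' Each category label's vector is a weighted sum of its superordinate-group
#' centroid, its subgroup centroid and label-specific noise, so cosine
#' similarity decreases from within-subgroup to across-group pairs.
#'
#' @param hierarchy A [category_hierarchy()].
#' @param dim Vector dimensionality.
#' @param seed Seed.
#' @param group_scale,subgroup_scale,noise_scale Component scales.
#' @return A labels x `dim` numeric matrix.
#' @export
make_label_vectors <- function(hierarchy = category_hierarchy(), dim = 50L,
                               seed = 1L, group_scale = 1,
                               subgroup_scale = 0.7, noise_scale = 0.5) {
  tab <- hierarchy$table
  if (anyDuplicated(tab$category)) .stopf("duplicate category labels")
  withr::with_seed(seed, {
    gmat <- matrix(stats::rnorm(length(unique(tab$group)) * dim), ncol = dim,
                   dimnames = list(unique(tab$group), NULL))
    smat <- matrix(stats::rnorm(length(unique(tab$subgroup)) * dim), ncol = dim,
                   dimnames = list(unique(tab$subgroup), NULL))
    vec <- group_scale * gmat[tab$group, , drop = FALSE] +
      subgroup_scale * smat[tab$subgroup, , drop = FALSE] +
      noise_scale * matrix(stats::rnorm(nrow(tab) * dim), ncol = dim)
    rownames(vec) <- tab$category
    vec
  })
}
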