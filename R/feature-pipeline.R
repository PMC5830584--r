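#' Canonical hemodynamic response kernel
#'
#' Double-gamma kernel: a response gamma density whose analytic mode sits
#' exactly at `peak_time` minus an undershoot gamma density (mode at
#' `3 * peak_time`) scaled by `undershoot_ratio`. The kernel is normalized to
#' unit peak amplitude and starts at exactly zero at t = 0.
#'
#' @param resolution Sampling step of the kernel taps, seconds.
#' @param peak_time Time of the peak response, seconds (default 4).
#' @param duration Kernel support, seconds.
#' @param undershoot_ratio Amplitude ratio of undershoot to response gamma.
#' @return An object of class `hrf_kernel` with fields `taps`, `resolution`
#'   and `peak_time`.
#' @export
hrf_kernel <- function(resolution, peak_time = 4, duration = 32,
                       undershoot_ratio = 1 / 6) {
  if (!is.finite(resolution) || resolution <= 0) .stopf("resolution must be > 0")
  if (!is.finite(peak_time) || peak_time <= 0) .stopf("peak_time must be > 0")
  t <- seq(0, duration, by = resolution)
  # gamma density with scale 1 has mode (shape - 1); shape = peak + 1 puts
  # the response mode exactly at peak_time
  h <- stats::dgamma(t, shape = peak_time + 1, scale = 1) -
    undershoot_ratio * stats::dgamma(t, shape = 3 * peak_time + 1, scale = 1)
  h <- h / max(h)
  structure(list(taps = h, resolution = resolution, peak_time = peak_time),
            class = "hrf_kernel")
}

#' Prepare a layered feature series for model fitting
#'
#' For time series: convolves every unit's activation with the hemodynamic
#' kernel (separately per session), downsamples to the TR grid by averaging
#' within TR windows, and standardizes each unit (zero mean, unit variance).
#' For static exemplar sets: standardizes only. When `standardizers` from a
#' previous (training) call are supplied they are reused, so test data are
#' scaled with training parameters and no information leaks.
#'
#' Zero-variance units are standardized to all-zero columns (guarded
#' division) and reported in the `flagged_units` attribute.
#'
#' @param features A [layered_features()].
#' @param kernel An [hrf_kernel()] sampled at the feature time step
#'   (ignored for static input).
#' @param tr Target sampling interval, seconds; must be a multiple of the
#'   feature time step.
#' @param standardizers Optional standardizers from a previous call
#'   (attribute `standardizers` of the returned object).
#' @return A standardized `layered_features` on the TR grid, with attribute
#'   `standardizers` (per-layer means and SDs) for reuse on test/exemplar
#'   data.
#' @export
prepare_series <- function(features, kernel = NULL, tr = NULL,
                           standardizers = NULL) {
  stopifnot(inherits(features, "layered_features"))
  static <- is.null(features$time_step)
  sessions <- features$sessions
  layers <- features$layers
  if (!static) {
    if (is.null(kernel) || is.null(tr)) .stopf("time series need kernel and tr")
    if (abs(kernel$resolution - features$time_step) > 1e-9)
      .stopf("kernel resolution must equal the feature time step")
    by <- tr / features$time_step
    if (abs(by - round(by)) > 1e-8) .stopf("time_step must divide tr")
    by <- as.integer(round(by))
    ids <- if (is.null(sessions)) rep(1L, nrow(layers[[1]])) else sessions
    layers <- lapply(layers, function(x) {
      do.call(rbind, lapply(unique(ids), function(s) {
        .downsample_rows(.convolve_cols(x[ids == s, , drop = FALSE], kernel$taps), by)
      }))
    })
    sessions <- rep(unique(ids), as.integer(table(factor(ids, unique(ids)))) %/% by)
  }
  fit_std <- is.null(standardizers)
  flagged <- list()
  std <- standardizers
  if (fit_std)
    std <- lapply(layers, function(x)
      list(mean = colMeans(x), sd = apply(x, 2L, stats::sd)))
  layers <- lapply(seq_along(layers), function(l) {
    x <- layers[[l]]
    if (ncol(x) != length(std[[l]]$mean))
      .stopf("standardizers do not match layer %d", l)
    sdv <- std[[l]]$sd
    zero <- sdv < .Machine$double.eps^0.5
    if (any(zero)) flagged[[length(flagged) + 1L]] <<- list(layer = l, units = which(zero))
    sdv[zero] <- Inf  # guarded division -> exact zeros
    sweep(sweep(x, 2L, std[[l]]$mean), 2L, sdv, "/")
  })
  out <- layered_features(layers,
                          time_step = if (static) NULL else tr,
                          sessions = sessions,
                          session_role = features$session_role)
  attr(out, "standardizers") <- std
  attr(out, "flagged_units") <- flagged
  out
}

#' Two-stage PCA of layered features
#'
#' Stage 1 reduces each layer separately: principal components are fitted on
#' the (centered) standardized layer matrix and the smallest number of
#' components explaining at least `variance_threshold` of the layer's
#' variance is retained. Stage 2 scales each layer's scores by
#' `1/sqrt(p_l)`, concatenates them across layers, and reduces again at the
#' same threshold.
#'
#' @param series A standardized [layered_features()] (training data).
#' @param variance_threshold Fraction of variance to retain at each stage,
#'   in (0, 1].
#' @return An object of class `pca_bases`: per-layer bases `layer_bases`
#'   (orthonormal columns), retained counts `layer_kept`, centering vectors
#'   `layer_means`, cross-layer basis `cross_basis`, `cross_kept`,
#'   `cross_mean`, per-stage explained-variance fractions, unit counts `p_l`
#'   and the threshold.
#' @export
fit_pca <- function(series, variance_threshold = 0.99) {
  stopifnot(inherits(series, "layered_features"))
  if (!is.numeric(variance_threshold) || variance_threshold <= 0 ||
      variance_threshold > 1)
    .stopf("variance_threshold must lie in (0, 1]")
  n <- nrow(series$layers[[1]])
  if (n < 2L) .stopf("at least 2 rows are required")
  p_l <- vapply(series$layers, ncol, integer(1))
  stage1 <- lapply(series$layers, function(x) {
    mu <- colMeans(x)
    xc <- sweep(x, 2L, mu)
    sv <- svd(xc)
    ev <- sv$d^2
    tot <- sum(ev)
    q <- if (tot <= 0) 1L else which(cumsum(ev) / tot >= variance_threshold - 1e-12)[1]
    list(mean = mu, basis = sv$v[, seq_len(q), drop = FALSE],
         explained = if (tot <= 0) 1 else sum(ev[seq_len(q)]) / tot,
         scores = sv$u[, seq_len(q), drop = FALSE] %*% diag(sv$d[seq_len(q)], q))
  })
  scaled <- lapply(seq_along(stage1), function(l) stage1[[l]]$scores / sqrt(p_l[l]))
  g <- do.call(cbind, scaled)
  mu_g <- colMeans(g)
  gc <- sweep(g, 2L, mu_g)
  sv <- svd(gc)
  ev <- sv$d^2
  tot <- sum(ev)
  k <- if (tot <= 0) 1L else which(cumsum(ev) / tot >= variance_threshold - 1e-12)[1]
  structure(list(
    layer_bases = lapply(stage1, `[[`, "basis"),
    layer_kept = vapply(stage1, function(s) ncol(s$basis), integer(1)),
    layer_means = lapply(stage1, `[[`, "mean"),
    layer_explained = vapply(stage1, `[[`, numeric(1), "explained"),
    cross_basis = sv$v[, seq_len(k), drop = FALSE],
    cross_kept = k,
    cross_mean = mu_g,
    cross_explained = if (tot <= 0) 1 else sum(ev[seq_len(k)]) / tot,
    p_l = p_l,
    variance_threshold = variance_threshold
  ), class = "pca_bases")
}

#' @export
print.pca_bases <- function(x, ...) {
  cat(sprintf("<pca_bases> %d layers, kept per layer: %s; cross-layer k = %d (threshold %.2f)\n",
              length(x$layer_bases), paste(x$layer_kept, collapse = "/"),
              x$cross_kept, x$variance_threshold))
  invisible(x)
}

#' Project layered features into the reduced design space
#'
#' Applies the two-stage PCA map fitted by [fit_pca()]: per-layer centering
#' and projection, `1/sqrt(p_l)` scaling, concatenation, cross-layer
#' centering and projection. Deterministic and (up to the tiny fitted
#' centering offsets of standardized data) linear.
#'
#' @param features A standardized [layered_features()] with layer shapes
#'   matching the fitted bases.
#' @param bases A [fit_pca()] result.
#' @return An object of class `feature_design` with the `N x k` design
#'   `matrix`, per-row `sessions` and the `tr`/`time_step` of the input.
#' @export
transform_features <- function(features, bases) {
  stopifnot(inherits(features, "layered_features"), inherits(bases, "pca_bases"))
  if (length(features$layers) != length(bases$layer_bases))
    .stopf("layer count mismatch")
  scaled <- lapply(seq_along(features$layers), function(l) {
    x <- features$layers[[l]]
    if (ncol(x) != nrow(bases$layer_bases[[l]]))
      .stopf("layer %d has %d units, bases expect %d", l, ncol(x),
             nrow(bases$layer_bases[[l]]))
    sweep(x, 2L, bases$layer_means[[l]]) %*% bases$layer_bases[[l]] /
      sqrt(bases$p_l[l])
  })
  g <- sweep(do.call(cbind, scaled), 2L, bases$cross_mean)
  structure(list(matrix = g %*% bases$cross_basis,
                 sessions = features$sessions,
                 session_role = features$session_role,
                 time_step = features$time_step,
                 cross_kept = bases$cross_kept),
            class = "feature_design")
}

#' Split a layered series into its train and test sessions
#'
#' @param features A [layered_features()] time series with session roles.
#' @return List with `layered_features` elements `train` and `test`;
#'   standardizer attributes are carried along.
#' @export
split_by_role <- function(features) {
  stopifnot(inherits(features, "layered_features"))
  if (is.null(features$sessions) || is.null(features$session_role))
    .stopf("features lack session/role structure")
  role <- features$session_role[as.character(features$sessions)]
  mk <- function(keep) {
    lf <- layered_features(lapply(features$layers, function(x) x[keep, , drop = FALSE]),
                           time_step = features$time_step,
                           sessions = features$sessions[keep],
                           session_role = features$session_role)
    attr(lf, "standardizers") <- attr(features, "standardizers")
    lf
  }
  list(train = mk(role == "train"), test = mk(role == "test"))
}

#' Prepare train and test sessions without leakage
#'
#' Convolves, downsamples and standardizes the training sessions, then
#' applies the training standardizers to the test sessions, so no test
#' statistic ever enters the preprocessing.
#'
#' @param features A raw [layered_features()] time series with session
#'   roles.
#' @param kernel,tr As in [prepare_series()].
#' @return List with prepared `train` and `test` series and the
#'   `standardizers` fitted on the training sessions.
#' @export
prepare_train_test <- function(features, kernel, tr) {
  halves <- split_by_role(features)
  train <- prepare_series(halves$train, kernel, tr)
  std <- attr(train, "standardizers")
  test <- prepare_series(halves$test, kernel, tr, standardizers = std)
  list(train = train, test = test, standardizers = std)
}

#' Zero all layers except one (single-layer ablation)
#'
#' Operates on standardized features, so ablated layers contribute exactly
#' zero to the downstream PCA projection and the per-layer designs sum to
#' the full design.
#'
#' @param features A standardized [layered_features()].
#' @param layer Index of the layer to keep.
#' @return A `layered_features` with every other layer set to exactly zero.
#' @export
ablate_to_layer <- function(features, layer) {
  stopifnot(inherits(features, "layered_features"))
  L <- length(features$layers)
  if (!.is_count(layer) || layer > L) .stopf("layer must be in 1..%d", L)
  out <- features
  for (l in seq_len(L)) if (l != layer) out$layers[[l]][] <- 0
  out
}
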