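#' Fit voxel-wise ridge encoding models
#'
#' Minimizes `(1/N) sum_i (r_v(x_i) - f(x_i) w_v)^2 + lambda ||w_v||^2` for
#' every voxel simultaneously via the SVD of the design. The regularization
#' parameter is chosen by k-fold cross-validation over contiguous time blocks
#' (respecting temporal autocorrelation), maximizing the mean held-out
#' prediction correlation. By default one lambda is shared by all voxels;
#' `per_voxel = TRUE` selects lambda per voxel.
#'
#' @param design A [transform_features()] design (N x k).
#' @param responses A [voxel_responses()] with N time points (standardized,
#'   repeat-averaged).
#' @param lambda_grid Candidate lambdas; default: 10 log-spaced points over
#'   six decades.
#' @param n_folds Number of cross-validation folds (default 9).
#' @param per_voxel Select lambda per voxel instead of one shared value.
#' @return An object of class `encoding_model`: `weights` (voxel x k),
#'   `lambda` (scalar or per-voxel), `cv_table` (lambda x fold mean
#'   correlation) and `cv_by_voxel` (lambda x voxel mean over folds).
#' @export
fit_ridge <- function(design, responses,
                      lambda_grid = 10^seq(-3, 3, length.out = 10),
                      n_folds = 9, per_voxel = FALSE) {
  stopifnot(inherits(design, "feature_design"), inherits(responses, "voxel_responses"))
  x <- design$matrix
  y <- t(responses$values)                     # N x V
  if (nrow(x) != nrow(y)) .stopf("design rows (%d) != response time points (%d)",
                                 nrow(x), nrow(y))
  if (!length(lambda_grid)) .stopf("lambda_grid must be non-empty")
  if (any(lambda_grid < 0)) .stopf("lambdas must be >= 0")
  n <- nrow(x)
  fold_id <- cut(seq_len(n), breaks = n_folds, labels = FALSE)
  n_lam <- length(lambda_grid)
  cv_table <- matrix(NA_real_, n_lam, n_folds,
                     dimnames = list(signif(lambda_grid, 4), NULL))
  cv_vox <- matrix(0, n_lam, ncol(y))
  for (f in seq_len(n_folds)) {
    tr <- fold_id != f
    fit <- .ridge_svd(x[tr, , drop = FALSE])
    uty <- crossprod(fit$u, y[tr, , drop = FALSE])
    xv <- x[!tr, , drop = FALSE] %*% fit$v
    for (j in seq_len(n_lam)) {
      pred <- xv %*% (.ridge_scale(fit$d, sum(tr), lambda_grid[j]) * uty)
      r <- .cor_cols(pred, y[!tr, , drop = FALSE])
      cv_vox[j, ] <- cv_vox[j, ] + r / n_folds
      cv_table[j, f] <- mean(r)
    }
  }
  fit <- .ridge_svd(x)
  uty <- crossprod(fit$u, y)
  if (per_voxel) {
    best <- apply(cv_vox, 2L, which.max)
    w <- matrix(0, ncol(x), ncol(y))
    for (j in unique(best)) {
      cols <- best == j
      w[, cols] <- fit$v %*% (.ridge_scale(fit$d, n, lambda_grid[j]) *
                                uty[, cols, drop = FALSE])
    }
    lambda <- lambda_grid[best]
  } else {
    j <- which.max(rowMeans(cv_table))
    w <- fit$v %*% (.ridge_scale(fit$d, n, lambda_grid[j]) * uty)
    lambda <- lambda_grid[j]
  }
  structure(list(weights = t(w), lambda = lambda, cv_table = cv_table,
                 cv_by_voxel = cv_vox, lambda_grid = lambda_grid,
                 n_obs = n),
            class = "encoding_model")
}

.ridge_svd <- function(x) {
  sv <- svd(x)
  keep <- sv$d > max(dim(x)) * .Machine$double.eps * max(sv$d, 1)
  list(u = sv$u[, keep, drop = FALSE], d = sv$d[keep],
       v = sv$v[, keep, drop = FALSE], rank = sum(keep),
       deficient = !all(keep))
}

.ridge_scale <- function(d, n, lambda) {
  if (lambda == 0 && length(d) == 0)
    warning("singular design at lambda = 0; pseudo-inverse solution returned")
  d / (d^2 + n * lambda)
}

#' @export
print.encoding_model <- function(x, ...) {
  lam <- if (length(x$lambda) == 1L) sprintf("lambda = %.4g", x$lambda) else
    sprintf("per-voxel lambda (median %.4g)", stats::median(x$lambda))
  cat(sprintf("<encoding_model> %d voxels x %d features, %s\n",
              nrow(x$weights), ncol(x$weights), lam))
  invisible(x)
}

#' Predict voxel responses from a design
#'
#' @param object An [fit_ridge()] model.
#' @param design A [transform_features()] design.
#' @param ... Unused.
#' @return A [voxel_responses()] of predictions (voxel x N).
#' @export
predict.encoding_model <- function(object, design, ...) {
  stopifnot(inherits(design, "feature_design"))
  if (ncol(design$matrix) != ncol(object$weights))
    .stopf("design columns (%d) do not match model features (%d)",
           ncol(design$matrix), ncol(object$weights))
  voxel_responses(values = object$weights %*% t(design$matrix),
                  sessions = if (is.null(design$sessions))
                    rep(1L, nrow(design$matrix)) else design$sessions,
                  tr = if (is.null(design$time_step)) NA_real_ else design$time_step)
}

#' Prediction accuracy per voxel
#'
#' Pearson correlation between predicted and observed series, evaluated
#' separately within each session and averaged across sessions.
#' Zero-variance series yield r = 0 and are flagged.
#'
#' @param predicted,observed [voxel_responses()] with matching shapes and
#'   session structure.
#' @return An object of class `accuracy_report`: `r` (per voxel),
#'   `r_by_session` (voxel x session) and `zero_variance` flags. Slots `p`,
#'   `q`, `ceiling`, `r_normalized` are filled by the dedicated estimators.
#' @export
prediction_accuracy <- function(predicted, observed) {
  stopifnot(inherits(predicted, "voxel_responses"), inherits(observed, "voxel_responses"))
  if (!identical(dim(predicted$values), dim(observed$values)))
    .stopf("predicted and observed shapes differ")
  if (!identical(as.integer(predicted$sessions), as.integer(observed$sessions)))
    .stopf("session structures differ")
  ids <- unique(observed$sessions)
  rbs <- matrix(NA_real_, nrow(observed$values), length(ids))
  zv <- rep(FALSE, nrow(observed$values))
  for (i in seq_along(ids)) {
    idx <- observed$sessions == ids[i]
    r <- .cor_cols(t(predicted$values[, idx, drop = FALSE]),
                   t(observed$values[, idx, drop = FALSE]))
    rbs[, i] <- r
    zv <- zv | attr(r, "zero_variance")
  }
  structure(list(r = rowMeans(rbs), r_by_session = rbs, sessions = ids,
                 zero_variance = zv, p = NULL, q = NULL, ceiling = NULL,
                 r_normalized = NULL),
            class = "accuracy_report")
}

#' Block-permutation significance test of prediction accuracy
#'
#' Builds a null distribution for each voxel's accuracy by permuting
#' contiguous blocks of the predicted series within each session (or
#' circularly shifting it) and recomputing the session-averaged correlation.
#' `p = (1 + #null >= observed) / (1 + n_perm)`.
#'
#' @param predicted,observed [voxel_responses()] as in
#'   [prediction_accuracy()].
#' @param block_length Block length in seconds (default 20, i.e. 10 TRs at
#'   TR = 2); must be at least `2 * tr`.
#' @param n_perm Number of permutations (>= 100).
#' @param scheme `"shuffle"` permutes block order; `"circular"` applies a
#'   random circular shift per session.
#' @param seed Seed for the permutation stream.
#' @return List with per-voxel `p`, the observed `r` and `n_perm`.
#' @export
block_permutation_test <- function(predicted, observed, block_length = 20,
                                   n_perm = 1000,
                                   scheme = c("shuffle", "circular"),
                                   seed = 1L) {
  scheme <- match.arg(scheme)
  tr <- observed$tr
  if (!is.finite(tr) || tr <= 0) tr <- 1
  if (block_length < 2 * tr) .stopf("block_length must be >= 2 * TR")
  if (n_perm < 100) .stopf("n_perm must be >= 100")
  m <- max(2L, as.integer(round(block_length / tr)))
  ids <- unique(observed$sessions)
  for (s in ids)
    if (sum(observed$sessions == s) < 2L * m)
      .stopf("session %s is shorter than two blocks", s)
  obs <- prediction_accuracy(predicted, observed)$r
  count <- rep(0L, length(obs))
  withr::with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm_pred <- predicted$values
      for (s in ids) {
        idx <- which(observed$sessions == s)
        ord <- .block_order(length(idx), m, scheme)
        perm_pred[, idx] <- perm_pred[, idx[ord], drop = FALSE]
      }
      null_r <- prediction_accuracy(
        voxel_responses(perm_pred, observed$sessions, observed$tr), observed)$r
      count <- count + (null_r >= obs)
    }
  })
  list(p = (1 + count) / (1 + n_perm), r = obs, n_perm = n_perm)
}

.block_order <- function(n, m, scheme) {
  if (scheme == "circular") {
    shift <- sample.int(n - 1L, 1L)
    return(c((shift + 1L):n, 1L:shift))
  }
  n_blocks <- ceiling(n / m)
  blocks <- split(seq_len(n), rep(seq_len(n_blocks), each = m)[seq_len(n)])
  unlist(blocks[sample.int(n_blocks)], use.names = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param p Vector of p-values.
#' @return FDR-adjusted q-values.
#' @export
fdr_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Monte-Carlo noise ceiling from response repeats
#'
#' For each test session the noise variance of the repeat-averaged series and
#' the mean/SD of the underlying signal are estimated per voxel (signal
#' variance = variance of the repeat mean minus noise variance / 1, floored
#' at zero after removing the averaged noise contribution). Both signal and
#' noise are modeled as Gaussian; each simulation draws a signal series and a
#' noisy copy, correlates them, and the median correlation over `n_sim`
#' simulations is the session ceiling, averaged across sessions.
#'
#' @param responses A [voxel_responses()] carrying a repeats array with at
#'   least 2 repeats.
#' @param n_sim Simulations per session (default 1000).
#' @param seed Seed.
#' @return Per-voxel noise ceiling in \[0, 1\].
#' @export
noise_ceiling <- function(responses, n_sim = 1000, seed = 1L) {
  stopifnot(inherits(responses, "voxel_responses"))
  reps <- responses$repeats
  if (is.null(reps) || dim(reps)[3] < 2L)
    .stopf("noise_ceiling needs >= 2 repeats; supply a voxel_responses with a repeats array")
  n_rep <- dim(reps)[3]
  ids <- unique(responses$sessions)
  ceil <- matrix(NA_real_, dim(reps)[1], length(ids))
  withr::with_seed(seed, {
    for (i in seq_along(ids)) {
      idx <- which(responses$sessions == ids[i])
      nt <- length(idx)
      for (v in seq_len(dim(reps)[1])) {
        x <- reps[v, idx, ]                     # time x repeat
        noise_var_avg <- mean(apply(x, 1L, stats::var)) / n_rep
        m <- rowMeans(x)
        sig_var <- max(stats::var(m) - noise_var_avg, 0)
        if (sig_var == 0) { ceil[v, i] <- 0; next }
        sig <- matrix(stats::rnorm(nt * n_sim, mean = mean(m), sd = sqrt(sig_var)), nt)
        dat <- sig + matrix(stats::rnorm(nt * n_sim, sd = sqrt(noise_var_avg)), nt)
        ceil[v, i] <- stats::median(.cor_cols(sig, dat))
      }
    }
  })
  pmin(pmax(rowMeans(ceil), 0), 1)
}

#' Variance explained per layer and layer assignment
#'
#' For each layer, test features are ablated to that layer, projected, and
#' predicted through the fitted model; the explained variance per voxel is
#' the session-averaged squared correlation between the single-layer
#' prediction and the observed response.
#'
#' @param model An [fit_ridge()] model.
#' @param bases The [fit_pca()] bases the model was trained with.
#' @param features Standardized test [layered_features()].
#' @param observed Observed test [voxel_responses()].
#' @return Voxel x layer matrix of explained variance (R^2).
#' @export
layer_explained_variance <- function(model, bases, features, observed) {
  L <- length(features$layers)
  r2 <- matrix(NA_real_, nrow(model$weights), L)
  for (l in seq_len(L)) {
    pred <- predict(model, transform_features(ablate_to_layer(features, l), bases))
    acc <- prediction_accuracy(pred, observed)
    r2[, l] <- rowMeans(acc$r_by_session^2)
  }
  colnames(r2) <- paste0("layer", seq_len(L))
  r2
}

#' Assign each voxel to its best-explained layer
#'
#' @param r2 Voxel x layer matrix from [layer_explained_variance()].
#' @param r2_floor Voxels whose maximum explained variance falls below this
#'   floor are flagged low-confidence.
#' @return List with integer `layer` (argmax, ties broken towards the lowest
#'   index) and logical `low_confidence`.
#' @export
assign_layer <- function(r2, r2_floor = 0.01) {
  best <- apply(r2, 1L, which.max)   # which.max takes the first (lowest) index
  list(layer = as.integer(best),
       low_confidence = apply(r2, 1L, max) < r2_floor)
}

#' Evaluate an encoding model on test data
#'
#' Convenience wrapper assembling the full accuracy report: session-averaged
#' correlation, block-permutation p and FDR q, Monte-Carlo noise ceiling and
#' ceiling-normalized accuracy.
#'
#' @param model,design Test design and fitted model.
#' @param observed Preprocessed observed test responses.
#' @param test_repeats A [voxel_responses()] with the raw test repeats (for
#'   the ceiling); `NULL` skips the ceiling.
#' @param n_perm,block_length,seed Passed to [block_permutation_test()].
#' @param n_sim Passed to [noise_ceiling()].
#' @return A complete `accuracy_report`.
#' @export
evaluate_encoding <- function(model, design, observed, test_repeats = NULL,
                              n_perm = 1000, block_length = 20, n_sim = 1000,
                              seed = 1L) {
  pred <- predict(model, design)
  report <- prediction_accuracy(pred, observed)
  bp <- block_permutation_test(pred, observed, block_length = block_length,
                               n_perm = n_perm, seed = seed)
  report$p <- bp$p
  report$q <- fdr_adjust(bp$p)
  if (!is.null(test_repeats)) {
    report$ceiling <- noise_ceiling(test_repeats, n_sim = n_sim, seed = seed + 1L)
    report$r_normalized <- ifelse(report$ceiling > 0, report$r / report$ceiling, NA_real_)
  }
  report
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> %d voxels, %d session(s); mean r = %.3f\n",
              length(x$r), ncol(x$r_by_session), mean(x$r)))
  if (!is.null(x$q))
    cat(sprintf("  %d voxels with q < 0.01\n", sum(x$q < 0.01)))
  invisible(x)
}
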