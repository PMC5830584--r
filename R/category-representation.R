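#' Model-synthesized map of one category
#'
#' Standardizes the category's exemplar features with the training
#' standardizers, projects them through the fitted PCA bases and encoding
#' model, and averages the simulated response maps over exemplars.
#'
#' @param model An [fit_ridge()] model.
#' @param bases The matching [fit_pca()] bases.
#' @param exemplars A static [layered_features()] of the category's
#'   exemplars.
#' @param standardizers Training standardizers from [prepare_series()].
#' @return List with `map` (per-voxel mean response) and `responses`
#'   (voxel x exemplar matrix of per-exemplar predictions).
#' @export
category_map <- function(model, bases, exemplars, standardizers) {
  stopifnot(inherits(exemplars, "layered_features"))
  if (!nrow(exemplars$layers[[1]])) .stopf("empty exemplar set")
  std <- prepare_series(exemplars, standardizers = standardizers)
  pred <- predict(model, transform_features(std, bases))$values
  list(map = rowMeans(pred), responses = pred)
}

#' Build a category atlas of model-synthesized representations
#'
#' Applies [category_map()] to every category of an exemplar set.
#'
#' @param model,bases,standardizers As in [category_map()].
#' @param exemplars A [make_category_exemplars()] result.
#' @return An object of class `category_atlas`: `maps` (category x voxel),
#'   `exemplar_responses` (per-category voxel x exemplar matrices),
#'   `exemplar_counts`, `categories` and the planted `hierarchy`.
#' @export
build_category_atlas <- function(model, bases, exemplars, standardizers) {
  stopifnot(inherits(exemplars, "category_exemplars"))
  per_cat <- lapply(exemplars$exemplar_features, category_map,
                    model = model, bases = bases, standardizers = standardizers)
  maps <- do.call(rbind, lapply(per_cat, `[[`, "map"))
  rownames(maps) <- exemplars$categories
  structure(list(maps = maps,
                 exemplar_responses = lapply(per_cat, `[[`, "responses"),
                 exemplar_counts = exemplars$exemplar_counts,
                 categories = exemplars$categories,
                 hierarchy = exemplars$hierarchy),
            class = "category_atlas")
}

#' @export
print.category_atlas <- function(x, ...) {
  cat(sprintf("<category_atlas> %d categories x %d voxels (%d exemplars total)\n",
              nrow(x$maps), ncol(x$maps), sum(x$exemplar_counts)))
  invisible(x)
}

#' Category selectivity (d-prime) per voxel
#'
#' For every voxel and category i, `d'_i = (mean_i - mean_ic) /
#' sqrt((var_i + var_ic) / 2)`, where the `i` statistics are over the
#' category's exemplar responses and the `ic` statistics pool the exemplars
#' of all other categories. The general selectivity of a voxel is its
#' maximal d' over categories.
#'
#' @param atlas A [build_category_atlas()] with per-exemplar responses.
#' @return An object of class `selectivity_profile`: `dprime_by_category`
#'   (voxel x category), `selectivity` (per-voxel max), `zero_variance`
#'   flags.
#' @export
category_dprime <- function(atlas) {
  stopifnot(inherits(atlas, "category_atlas"))
  resp <- atlas$exemplar_responses
  if (any(vapply(resp, ncol, integer(1)) < 2L))
    .stopf("every category needs >= 2 exemplars for d-prime")
  n_vox <- nrow(resp[[1]])
  counts <- vapply(resp, ncol, integer(1))
  sums <- do.call(cbind, lapply(resp, rowSums))              # voxel x category
  sqs <- do.call(cbind, lapply(resp, function(m) rowSums(m^2)))
  tot_n <- sum(counts)
  tot_sum <- rowSums(sums)
  tot_sq <- rowSums(sqs)
  d <- matrix(NA_real_, n_vox, length(resp),
              dimnames = list(NULL, atlas$categories))
  flag <- matrix(FALSE, n_vox, length(resp))
  for (i in seq_along(resp)) {
    n_i <- counts[i]
    m_i <- sums[, i] / n_i
    v_i <- (sqs[, i] - n_i * m_i^2) / (n_i - 1L)
    n_c <- tot_n - n_i
    m_c <- (tot_sum - sums[, i]) / n_c
    v_c <- (tot_sq - sqs[, i] - n_c * m_c^2) / (n_c - 1L)
    pooled <- (pmax(v_i, 0) + pmax(v_c, 0)) / 2
    zero <- pooled < .Machine$double.eps
    d[, i] <- ifelse(zero, 0, (m_i - m_c) / sqrt(pooled))
    flag[, i] <- zero
  }
  structure(list(dprime_by_category = d,
                 selectivity = apply(d, 1L, max),
                 zero_variance = flag),
            class = "selectivity_profile")
}

#' Ranked category profile of one voxel
#'
#' Lists the categories in descending order of their synthesized response at
#' the voxel; ties are broken alphabetically (stable).
#'
#' @param atlas A [build_category_atlas()].
#' @param voxel Voxel index.
#' @param top_k Number of labels to return (truncated to the category
#'   count).
#' @return Character vector of category labels, strongest first.
#' @export
selectivity_profile <- function(atlas, voxel, top_k = 10) {
  stopifnot(inherits(atlas, "category_atlas"))
  vals <- atlas$maps[, voxel]
  ord <- order(-vals, atlas$categories)
  atlas$categories[ord][seq_len(min(top_k, length(vals)))]
}

#' ROI-level selectivity summary
#'
#' @param selectivity Per-voxel selectivity (e.g. from [category_dprime()]).
#' @param roi_labels Per-voxel ROI label; `NA` voxels are ignored.
#' @return Data frame with per-ROI `mean`, `se`, voxel count `n` and a
#'   `single_voxel` flag (SE reported as 0 for single-voxel ROIs).
#' @export
roi_selectivity <- function(selectivity, roi_labels) {
  if (length(selectivity) != length(roi_labels))
    .stopf("selectivity and roi_labels lengths differ")
  rois <- unique(stats::na.omit(roi_labels))
  out <- lapply(rois, function(roi) {
    x <- selectivity[!is.na(roi_labels) & roi_labels == roi]
    data.frame(roi = roi, mean = mean(x),
               se = if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0,
               n = length(x), single_voxel = length(x) == 1L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
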