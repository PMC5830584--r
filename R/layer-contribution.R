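#' Category maps attributed to a single feature layer
#'
#' For every category, keeps the exemplar features of one layer only
#' (zeroing all others in standardized space), projects them through the
#' trained encoding model and averages over exemplars. By linearity of the
#' model, the per-layer maps sum to the full-model maps.
#'
#' @param model,bases,standardizers As in [build_category_atlas()].
#' @param exemplars A [make_category_exemplars()] result.
#' @param layer Layer index to keep.
#' @return Category x voxel matrix of single-layer maps.
#' @export
layerwise_category_maps <- function(model, bases, exemplars, standardizers,
                                    layer) {
  stopifnot(inherits(exemplars, "category_exemplars"))
  maps <- do.call(rbind, lapply(exemplars$exemplar_features, function(ex) {
    std <- prepare_series(ex, standardizers = standardizers)
    abl <- ablate_to_layer(std, layer)
    rowMeans(predict(model, transform_features(abl, bases))$values)
  }))
  rownames(maps) <- exemplars$categories
  maps
}

#' Layer-wise contribution profile
#'
#' Re-evaluates the inter-category similarity network, the signed modularity
#' of a fixed cluster partition, and the cortical-semantic correlation, for
#' the maps attributed to each single layer.
#'
#' @param model,bases,standardizers,exemplars As in
#'   [layerwise_category_maps()].
#' @param mask Predictable-voxel mask for the similarity computation.
#' @param cluster_labels Fixed partition at which per-layer Q is evaluated
#'   (the full-model clustering by default framing).
#' @param semantics Named list of [semantic_matrix()] objects (e.g.
#'   `list(lch = ..., cosine = ...)`); may be empty.
#' @param n_perm Permutations for each semantic correlation.
#' @param seed Seed.
#' @return An object of class `layer_profile`: `table` (one row per layer
#'   with Q and per-method r/p), `argmax_Q_layer`, `argmax_r_layer` (per
#'   method; ties towards the lowest layer), and the per-layer similarity
#'   networks.
#' @export
layer_profile <- function(model, bases, exemplars, standardizers, mask,
                          cluster_labels, semantics = list(),
                          n_perm = 1000, seed = 1L) {
  L <- length(bases$layer_bases)
  nets <- vector("list", L)
  tab <- data.frame(layer = seq_len(L), Q = NA_real_)
  for (m in names(semantics)) {
    tab[[paste0("r_", m)]] <- NA_real_
    tab[[paste0("p_", m)]] <- NA_real_
  }
  for (l in seq_len(L)) {
    maps <- layerwise_category_maps(model, bases, exemplars, standardizers, l)
    net <- similarity_matrix(maps, mask)
    nets[[l]] <- net
    tab$Q[l] <- signed_modularity(net, cluster_labels)$Q
    for (m in names(semantics)) {
      rs <- representational_semantic_correlation(net, semantics[[m]],
                                                  n_perm = n_perm,
                                                  seed = seed + l)
      tab[[paste0("r_", m)]][l] <- rs$r
      tab[[paste0("p_", m)]][l] <- rs$p
    }
  }
  argmax_r <- lapply(names(semantics), function(m) which.max(tab[[paste0("r_", m)]]))
  names(argmax_r) <- names(semantics)
  structure(list(table = tab, argmax_Q_layer = which.max(tab$Q),
                 argmax_r_layer = argmax_r, networks = nets),
            class = "layer_profile")
}

#' @export
print.layer_profile <- function(x, ...) {
  cat(sprintf("<layer_profile> %d layers; argmax-Q layer = %d\n",
              nrow(x$table), x$argmax_Q_layer))
  print(x$table, row.names = FALSE)
  invisible(x)
}
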