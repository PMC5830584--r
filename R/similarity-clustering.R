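#' Mask of predictable voxels
#'
#' Voxels with FDR q below `q_threshold` and prediction accuracy strictly
#' above `r_threshold`.
#'
#' @param report A complete `accuracy_report` (with `q` filled in).
#' @param q_threshold,r_threshold Defaults q < 0.01 and r > 0.2.
#' @return Logical voxel mask.
#' @export
predictable_mask <- function(report, q_threshold = 0.01, r_threshold = 0.2) {
  stopifnot(inherits(report, "accuracy_report"))
  if (is.null(report$q)) .stopf("report lacks q values; run the permutation test first")
  mask <- report$q < q_threshold & report$r > r_threshold
  if (!any(mask))
    .stopf("no predictable voxels at q < %g and r > %g (max r = %.3f, min q = %.3g)",
           q_threshold, r_threshold, max(report$r), min(report$q))
  mask
}

#' Inter-category representational similarity network
#'
#' Pearson correlation of the spatial category maps across the masked
#' (predictable) voxels, viewed as a signed weighted undirected network.
#'
#' @param atlas A [build_category_atlas()], or a plain category x voxel map
#'   matrix.
#' @param mask Logical or integer voxel selector (default: all voxels).
#' @return An object of class `similarity_network`: symmetric `S` with unit
#'   diagonal, the positive/negative off-diagonal parts `S_plus`/`S_minus`,
#'   and zero-variance flags.
#' @export
similarity_matrix <- function(atlas, mask = NULL) {
  maps <- if (inherits(atlas, "category_atlas")) atlas$maps else as.matrix(atlas)
  if (is.null(mask)) mask <- rep(TRUE, ncol(maps))
  sub <- maps[, mask, drop = FALSE]
  if (ncol(sub) < 3L) .stopf("at least 3 masked voxels are required")
  sdv <- apply(sub, 1L, stats::sd)
  zero <- sdv < .Machine$double.eps^0.5
  s <- matrix(0, nrow(sub), nrow(sub), dimnames = list(rownames(maps), rownames(maps)))
  ok <- !zero
  if (sum(ok) >= 2L) s[ok, ok] <- stats::cor(t(sub[ok, , drop = FALSE]))
  diag(s) <- 1
  off <- s; diag(off) <- 0
  structure(list(S = s, S_plus = pmax(off, 0), S_minus = pmax(-off, 0),
                 zero_variance = zero, n_voxels = ncol(sub)),
            class = "similarity_network")
}

#' @export
print.similarity_network <- function(x, ...) {
  cat(sprintf("<similarity_network> %d categories over %d voxels; mean |S| = %.3f\n",
              nrow(x$S), x$n_voxels, mean(abs(x$S[upper.tri(x$S)]))))
  invisible(x)
}

# Modularity of a non-negative weight matrix (zero diagonal) at a partition.
# p_ij = W_ij / W_tot and q_ij = (rowsum_i / W_tot)(colsum_j / W_tot) with
# W_tot the total over ordered off-diagonal pairs, so both p and q sum to 1
# over all ordered pairs and a single-cluster partition scores exactly 0.
.modularity_part <- function(w, labels) {
  tot <- sum(w)
  if (tot <= 0) return(0)
  p <- w / tot
  rs <- rowSums(p)
  cs <- colSums(p)
  q <- 0
  for (cl in unique(labels)) {
    idx <- labels == cl
    q <- q + sum(p[idx, idx]) - sum(rs[idx]) * sum(cs[idx])
  }
  q
}

#' Signed modularity of a category partition
#'
#' Computes `Q = sum_ij (p_ij - q_ij) delta(C_i, C_j)` separately on the
#' positive and negative parts of the similarity network and combines them
#' by weight mass:
#' `Q = S+/(S+ + S-) * Q+  -  S-/(S+ + S-) * Q-`.
#' Diagonal self-similarities carry no edge weight.
#'
#' @param net A [similarity_matrix()] network.
#' @param labels Integer cluster label per category.
#' @return List with `Q`, `Q_plus`, `Q_minus` and the weight masses
#'   `S_plus_total`, `S_minus_total`; all-zero networks return Q = 0 with a
#'   `degenerate` flag.
#' @export
signed_modularity <- function(net, labels) {
  stopifnot(inherits(net, "similarity_network"))
  if (length(labels) != nrow(net$S)) .stopf("one label per category is required")
  qp <- .modularity_part(net$S_plus, labels)
  qm <- .modularity_part(net$S_minus, labels)
  sp <- sum(net$S_plus)
  sm <- sum(net$S_minus)
  if (sp + sm <= 0)
    return(list(Q = 0, Q_plus = 0, Q_minus = 0, S_plus_total = 0,
                S_minus_total = 0, degenerate = TRUE))
  list(Q = sp / (sp + sm) * qp - sm / (sp + sm) * qm,
       Q_plus = qp, Q_minus = qm,
       S_plus_total = sp, S_minus_total = sm, degenerate = FALSE)
}

#' Cluster categories by k-means with modularity model selection
#'
#' For each candidate k, runs k-means on the rows of the similarity matrix
#' (each category's similarity profile) with random restarts, keeps the
#' labeling with maximal signed modularity, and finally selects the k
#' maximizing Q (ties towards the smallest k).
#'
#' @param net A [similarity_matrix()] network.
#' @param k_range Candidate cluster counts (must stay below the category
#'   count).
#' @param n_restarts k-means restarts per k.
#' @param seed Seed making the search deterministic.
#' @return An object of class `clustering_result`: `labels`, `k`, `Q`,
#'   `Q_plus`, `Q_minus`, the `(k, Q)` scan table `k_scan` and an `unstable`
#'   flag for structureless networks.
#' @export
cluster_categories <- function(net, k_range = 2:8, n_restarts = 50, seed = 1L) {
  stopifnot(inherits(net, "similarity_network"))
  n <- nrow(net$S)
  k_range <- k_range[k_range >= 2 & k_range <= n - 1L]
  if (!length(k_range)) .stopf("k_range must contain values in 2..%d", n - 1L)
  if (!all(is.finite(net$S))) .stopf("similarity matrix contains non-finite values")
  best <- NULL
  k_scan <- data.frame(k = k_range, Q = NA_real_)
  withr::with_seed(seed, {
    for (i in seq_along(k_range)) {
      k <- k_range[i]
      best_k <- NULL
      for (rs in seq_len(n_restarts)) {
        km <- tryCatch(
          suppressWarnings(stats::kmeans(net$S, centers = k, nstart = 1L)),
          error = function(e) NULL)
        if (is.null(km)) next
        q <- signed_modularity(net, km$cluster)
        if (is.null(best_k) || q$Q > best_k$Q_all$Q)
          best_k <- list(labels = km$cluster, Q_all = q)
      }
      if (is.null(best_k)) next
      k_scan$Q[i] <- best_k$Q_all$Q
      if (is.null(best) || best_k$Q_all$Q > best$Q_all$Q + 1e-12)
        best <- c(best_k, list(k = k))
    }
  })
  if (is.null(best)) .stopf("clustering failed for every k; degenerate similarity matrix")
  structure(list(labels = unname(best$labels), k = best$k,
                 Q = best$Q_all$Q, Q_plus = best$Q_all$Q_plus,
                 Q_minus = best$Q_all$Q_minus, k_scan = k_scan,
                 unstable = max(k_scan$Q, na.rm = TRUE) < 1e-3),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("<clustering_result> k = %d, Q = %.4f (Q+ = %.4f, Q- = %.4f)%s\n",
              x$k, x$Q, x$Q_plus, x$Q_minus,
              if (isTRUE(x$unstable)) " [unstable: no structure]" else ""))
  invisible(x)
}

#' Permutation test of the modularity index
#'
#' Null distribution obtained by shuffling the pair-wise similarities (the
#' off-diagonal weights, signs shuffled jointly, symmetry preserved) and
#' recomputing Q at the given partition.
#'
#' @param net A [similarity_matrix()] network.
#' @param labels Partition whose Q is tested.
#' @param n_perm Number of shuffles (>= 100; the full-scale analysis uses
#'   1e5, desk-scale default 1e4).
#' @param seed Seed.
#' @return List with `p`, observed `Q` and the null mean/sd.
#' @export
modularity_permutation_test <- function(net, labels, n_perm = 10000, seed = 1L) {
  stopifnot(inherits(net, "similarity_network"))
  if (n_perm < 100) .stopf("n_perm must be >= 100")
  q_obs <- signed_modularity(net, labels)$Q
  n <- nrow(net$S)
  ut <- upper.tri(net$S)
  vals <- net$S[ut]
  null_q <- numeric(n_perm)
  withr::with_seed(seed, {
    for (b in seq_len(n_perm)) {
      s <- matrix(0, n, n)
      s[ut] <- sample(vals)
      s <- s + t(s)
      diag(s) <- 1
      off <- s; diag(off) <- 0
      net_b <- structure(list(S = s, S_plus = pmax(off, 0),
                              S_minus = pmax(-off, 0)),
                         class = "similarity_network")
      null_q[b] <- signed_modularity(net_b, labels)$Q
    }
  })
  list(p = (1 + sum(null_q >= q_obs)) / (1 + n_perm), Q = q_obs,
       null_mean = mean(null_q), null_sd = stats::sd(null_q))
}

#' Cluster-specific cortical region
#'
#' Voxels whose synthesized activation is significantly higher for the
#' exemplars of one cluster's categories than for random, non-selective
#' objects (per-voxel two-sample pooled-variance t-test, Bonferroni
#' corrected over voxels).
#'
#' @param atlas A [build_category_atlas()] with exemplar responses.
#' @param cluster_labels Per-category cluster labels.
#' @param cluster_id Which cluster's region to compute.
#' @param random_responses Voxel x object matrix of model responses to
#'   random exemplars (e.g. `category_map()$responses` on
#'   [make_random_exemplars()] output); needs >= 2 objects.
#' @param alpha Bonferroni-corrected significance level (default 0.01).
#' @return Logical voxel mask, with attributes `t` and `p_bonferroni`.
#' @export
cluster_specific_region <- function(atlas, cluster_labels, cluster_id,
                                    random_responses, alpha = 0.01) {
  stopifnot(inherits(atlas, "category_atlas"))
  if (ncol(random_responses) < 2L) .stopf("need >= 2 random objects")
  in_cluster <- which(cluster_labels == cluster_id)
  if (!length(in_cluster)) .stopf("cluster %s has no categories", cluster_id)
  a <- do.call(cbind, atlas$exemplar_responses[in_cluster])  # voxel x n1
  b <- random_responses
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1L)
  v2 <- rowSums((b - m2)^2) / (n2 - 1L)
  sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
  tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(abs(tstat), df = n1 + n2 - 2L, lower.tail = FALSE)
  p_adj <- pmin(p * length(p), 1)
  mask <- p_adj < alpha & m1 > m2
  attr(mask, "t") <- tstat
  attr(mask, "p_bonferroni") <- p_adj
  mask
}

#' Sub-cluster categories within a cluster-specific region
#'
#' Restricts the similarity analysis to the region's voxels and the
#' cluster's categories and re-runs [cluster_categories()].
#'
#' @param atlas A [build_category_atlas()].
#' @param region_mask Voxel mask from [cluster_specific_region()].
#' @param categories Indices or names of the cluster's categories.
#' @param k_range,n_restarts,seed Passed to [cluster_categories()].
#' @return A `clustering_result` over the selected categories, with the
#'   restricted `similarity_network` attached as attribute `network`.
#' @export
subcluster <- function(atlas, region_mask, categories, k_range = 2:8,
                       n_restarts = 50, seed = 1L) {
  stopifnot(inherits(atlas, "category_atlas"))
  if (!any(region_mask)) .stopf("region mask is empty")
  if (is.character(categories)) categories <- match(categories, atlas$categories)
  if (length(categories) < 3L) .stopf("need >= 3 categories to sub-cluster")
  net <- similarity_matrix(atlas$maps[categories, , drop = FALSE], region_mask)
  res <- cluster_categories(net, k_range = k_range, n_restarts = n_restarts,
                            seed = seed)
  attr(res, "network") <- net
  res
}
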