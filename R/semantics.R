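#' Leacock-Chodorow similarity between two labels
#'
#' `s = -log(p / (2 d))` where `p` is the length of the shortest is-a path
#' connecting the labels (node-counting convention: identical labels give
#' p = 1, siblings sharing a parent give p = 3) and `d` is the maximum depth
#' of the taxonomy in edge levels below the root. An `"edge"` convention
#' (p = edge count, identical labels handled as p = 1) is available.
#'
#' @param tax A [taxonomy()].
#' @param a,b Labels; both must resolve to taxonomy nodes.
#' @param convention `"node"` (default, classical) or `"edge"` path counting.
#' @return Similarity `s >= 0`.
#' @export
lch_similarity <- function(tax, a, b, convention = c("node", "edge")) {
  convention <- match.arg(convention)
  stopifnot(inherits(tax, "taxonomy"))
  for (lbl in c(a, b)) if (!lbl %in% tax$nodes) .stopf("label '%s' not in taxonomy", lbl)
  d <- tax$depth
  edge_dist <- as.numeric(igraph::distances(tax$graph, v = a, to = b, mode = "all"))
  p <- if (convention == "node") edge_dist + 1 else max(edge_dist, 1)
  -log(p / (2 * d))
}

#' Cosine similarity between two label vectors
#'
#' @param vectors Label-indexed matrix (rows = labels).
#' @param a,b Row labels.
#' @return Cosine of the angle between the two vectors, in \[-1, 1\].
#' @export
vector_cosine <- function(vectors, a, b) {
  for (lbl in c(a, b)) if (!lbl %in% rownames(vectors))
    .stopf("label '%s' not in vector table", lbl)
  va <- vectors[a, ]; vb <- vectors[b, ]
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) .stopf("zero vector for '%s'", if (na == 0) a else b)
  sum(va * vb) / (na * nb)
}

#' Inter-label semantic similarity matrix
#'
#' @param labels Character vector of labels.
#' @param method `"lch"` (taxonomy-based) or `"cosine"` (vector-based).
#' @param taxonomy A [taxonomy()] (for `"lch"`).
#' @param vectors Label-indexed vector matrix (for `"cosine"`).
#' @return An object of class `semantic_similarity` with the symmetric
#'   `matrix` and the `method`.
#' @export
semantic_matrix <- function(labels, method = c("lch", "cosine"),
                            taxonomy = NULL, vectors = NULL) {
  method <- match.arg(method)
  n <- length(labels)
  m <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  if (method == "lch") {
    if (is.null(taxonomy)) .stopf("lch needs a taxonomy")
    dist <- igraph::distances(taxonomy$graph, v = labels, to = labels, mode = "all")
    m[] <- -log((dist + 1) / (2 * taxonomy$depth))
  } else {
    if (is.null(vectors)) .stopf("cosine needs a vector table")
    for (i in seq_len(n)) for (j in i:n)
      m[i, j] <- m[j, i] <- vector_cosine(vectors, labels[i], labels[j])
  }
  structure(list(matrix = m, method = method), class = "semantic_similarity")
}

#' Correlation between cortical and semantic similarity
#'
#' Fisher z-transforms the cortical similarities (clipped at |r| = 1 - 1e-7),
#' correlates the upper-triangle values with the raw semantic similarities,
#' and assesses significance by jointly permuting the rows and columns of
#' the cortical matrix (label permutation) `n_perm` times;
#' `p = (1 + #null >= r) / (1 + n_perm)`.
#'
#' @param net A [similarity_matrix()] cortical network (or any
#'   `similarity_network`).
#' @param sem A [semantic_matrix()] with identical label order.
#' @param n_perm Number of label permutations (default 10000).
#' @param seed Seed.
#' @return List with `r`, `p`, `n_perm` and the permutation `null` vector.
#' @export
representational_semantic_correlation <- function(net, sem, n_perm = 10000,
                                                  seed = 1L) {
  stopifnot(inherits(net, "similarity_network"), inherits(sem, "semantic_similarity"))
  s <- net$S
  if (!identical(dim(s), dim(sem$matrix))) .stopf("matrix sizes differ")
  if (!is.null(rownames(s)) && !is.null(rownames(sem$matrix)) &&
      !identical(rownames(s), rownames(sem$matrix)))
    .stopf("label order differs between cortical and semantic matrices")
  clip <- 1 - 1e-7
  if (any(abs(s[upper.tri(s)]) > clip))
    warning("|r| = 1 cortical similarities clipped before Fisher z")
  z <- atanh(pmin(pmax(s, -clip), clip))
  ut <- upper.tri(z)
  r_obs <- stats::cor(z[ut], sem$matrix[ut])
  null <- numeric(n_perm)
  n <- nrow(z)
  withr::with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n)
      zp <- z[perm, perm]
      null[b] <- stats::cor(zp[ut], sem$matrix[ut])
    }
  })
  list(r = r_obs, p = (1 + sum(null >= r_obs)) / (1 + n_perm),
       n_perm = n_perm, null = null)
}
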