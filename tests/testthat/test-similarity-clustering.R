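test_that("predictable_mask applies strict thresholds", {
  rep0 <- structure(list(r = c(0.5, 0.2, 0.3, 0.1), q = c(0.001, 0.001, 0.5, 0.001)),
                    class = "accuracy_report")
  expect_identical(predictable_mask(rep0), c(TRUE, FALSE, FALSE, FALSE))
  # r = 0.2 exactly is excluded; q = threshold exactly is excluded
  rep1 <- structure(list(r = rep(0.5, 3), q = c(0.0099, 0.01, 0.02)),
                    class = "accuracy_report")
  expect_identical(predictable_mask(rep1), c(TRUE, FALSE, FALSE))
  rep2 <- structure(list(r = rep(0, 3), q = rep(1, 3)), class = "accuracy_report")
  expect_error(predictable_mask(rep2), "no predictable voxels")
  # brute-force filter agreement on a random fixture
  withr::with_seed(1, {
    r <- runif(20, 0, 0.6); q <- runif(20, 0, 0.05)
  })
  rep3 <- structure(list(r = r, q = q), class = "accuracy_report")
  expect_identical(predictable_mask(rep3),
                   sapply(1:20, function(i) q[i] < 0.01 && r[i] > 0.2))
})

test_that("similarity_matrix is a signed correlation network", {
  maps <- rbind(a = c(1, 2, 3, 4, 5), b = c(2, 4, 6, 8, 10),
                c = -c(1, 2, 3, 4, 5), d = c(5, 1, 4, 2, 3))
  net <- similarity_matrix(maps)
  expect_equal(net$S["a", "b"], 1)
  expect_equal(net$S["a", "c"], -1)
  expect_equal(diag(net$S), rep(1, 4), ignore_attr = TRUE)
  expect_equal(net$S, t(net$S))
  expect_equal(net$S - diag(4), net$S_plus - net$S_minus, ignore_attr = TRUE)
  expect_true(all(net$S_plus >= 0) && all(net$S_minus >= 0))
  # independent covariance-based oracle
  oracle <- stats::cov(t(maps)) /
    tcrossprod(apply(maps, 1, sd))
  expect_equal(net$S[upper.tri(net$S)], oracle[upper.tri(oracle)],
               tolerance = 1e-12)
  # zero-variance map flagged with zero similarity
  maps2 <- rbind(maps, e = rep(1, 5))
  net2 <- similarity_matrix(maps2)
  expect_true(net2$zero_variance["e"])
  expect_equal(unname(net2$S["e", c("a", "b", "c", "d")]), rep(0, 4))
  expect_error(similarity_matrix(maps[, 1:2]), "3 masked voxels")
})

test_that("signed modularity matches the definition term by term", {
  # single cluster: p and q both sum to 1 -> Q+ exactly 0
  s <- random_similarity(6, seed = 2)
  net <- as_network(s)
  one <- signed_modularity(net, rep(1, 6))
  expect_equal(one$Q_plus, 0, tolerance = 1e-12)
  expect_equal(one$Q_minus, 0, tolerance = 1e-12)

  # 4-node two-cluster positive network evaluated by hand:
  # unit within-cluster weights only -> perfect assortative partition
  s4 <- diag(4)
  s4[1, 2] <- s4[2, 1] <- 1
  s4[3, 4] <- s4[4, 3] <- 1
  q4 <- signed_modularity(as_network(s4), c(1, 1, 2, 2))
  expect_equal(q4$Q, brute_modularity(s4, c(1, 1, 2, 2)), tolerance = 1e-12)
  expect_equal(q4$Q, 0.5, tolerance = 1e-12)  # 1 - 2 * (1/2)^2

  # random signed instances against the brute-force oracle
  for (seed in 3:7) {
    s <- random_similarity(7, sd = 0.5, seed = seed)
    labels <- withr::with_seed(seed, sample(1:3, 7, replace = TRUE))
    expect_equal(signed_modularity(as_network(s), labels)$Q,
                 brute_modularity(s, labels), tolerance = 1e-12)
  }

  # decomposition identity Q = w+ Q+ - w- Q-
  s <- random_similarity(9, sd = 0.5, seed = 11)
  net <- as_network(s)
  labels <- rep(1:3, each = 3)
  m <- signed_modularity(net, labels)
  wp <- m$S_plus_total / (m$S_plus_total + m$S_minus_total)
  expect_equal(m$Q, wp * m$Q_plus - (1 - wp) * m$Q_minus, tolerance = 1e-12)

  # all-zero weights -> flagged Q = 0
  z <- signed_modularity(as_network(diag(5)), rep(1:5))
  expect_true(z$degenerate)
  expect_identical(z$Q, 0)

  # random labels have null mean Q ~ 0
  s <- random_similarity(12, sd = 0.4, seed = 13)
  net <- as_network(s)
  qs <- withr::with_seed(14, replicate(1000,
    signed_modularity(net, sample(1:3, 12, replace = TRUE))$Q))
  expect_lt(abs(mean(qs)), 3 * sd(qs) / sqrt(1000))
})

test_that("cluster_categories recovers planted blocks and selects k by Q", {
  # planted 3-block similarity: within 0.5, between 0, noise sd 0.05
  n <- 30
  blocks <- rep(1:3, each = 10)
  withr::with_seed(7, {
    s <- 0.5 * outer(blocks, blocks, "==") +
      matrix(rnorm(n * n, sd = 0.05), n, n)
  })
  s <- (s + t(s)) / 2
  diag(s) <- 1
  net <- as_network(s)
  res <- cluster_categories(net, seed = 7)
  expect_identical(res$k, 3L)
  expect_equal(adjusted_rand(res$labels, blocks), 1)
  expect_false(res$unstable)

  # determinism under the seed
  res2 <- cluster_categories(net, seed = 7)
  expect_identical(res$labels, res2$labels)

  # constant off-diagonal similarity: no exploitable structure, flagged
  # unstable (Q is slightly negative, never positive, for uniform weights)
  flat <- matrix(0.4, 8, 8)
  diag(flat) <- 1
  resf <- cluster_categories(as_network(flat), k_range = 2:4, seed = 1)
  expect_true(resf$unstable)
  expect_lt(max(resf$k_scan$Q), 1e-10)
  expect_lt(max(abs(resf$k_scan$Q)), 0.1)

  expect_error(cluster_categories(net, k_range = 40:50), "k_range")
})

test_that("selected partition attains the exhaustive maximum (n = 7)", {
  withr::with_seed(21, {
    blocks <- c(1, 1, 2, 2, 3, 3, 3)
    s <- 0.6 * outer(blocks, blocks, "==") + matrix(rnorm(49, sd = 0.05), 7, 7)
  })
  s <- (s + t(s)) / 2
  diag(s) <- 1
  net <- as_network(s)
  res <- cluster_categories(net, k_range = 2:4, n_restarts = 100, seed = 3)
  parts <- all_partitions(7, max_blocks = 4)
  q_best <- max(vapply(parts, function(p) brute_modularity(s, p), numeric(1)))
  expect_equal(res$Q, q_best, tolerance = 1e-10)
})

test_that("clustering is equivariant under category reordering", {
  n <- 12
  blocks <- rep(1:3, each = 4)
  withr::with_seed(5, {
    s <- 0.5 * outer(blocks, blocks, "==") + matrix(rnorm(n * n, sd = 0.05), n, n)
    perm <- sample.int(n)
  })
  s <- (s + t(s)) / 2; diag(s) <- 1
  res1 <- cluster_categories(as_network(s), k_range = 2:4, seed = 9)
  res2 <- cluster_categories(as_network(s[perm, perm]), k_range = 2:4, seed = 9)
  expect_equal(adjusted_rand(res1$labels[perm], res2$labels), 1)
})

test_that("modularity permutation test: extremes and invariances", {
  n <- 12
  blocks <- rep(1:3, each = 4)
  withr::with_seed(6, s <- 0.7 * outer(blocks, blocks, "==") +
                     matrix(rnorm(n * n, sd = 0.03), n, n))
  s <- (s + t(s)) / 2; diag(s) <- 1
  net <- as_network(s)
  pt <- modularity_permutation_test(net, blocks, n_perm = 199, seed = 1)
  expect_equal(pt$p, 1 / 200)
  # invariance to category reordering
  perm <- withr::with_seed(2, sample.int(n))
  pt2 <- modularity_permutation_test(as_network(s[perm, perm]), blocks[perm],
                                     n_perm = 199, seed = 1)
  expect_equal(pt$p, pt2$p)
})

test_that("cluster-specific regions: t oracle, null calibration, recovery", {
  # hand-computed pooled-variance t on a 6-value fixture
  a <- matrix(c(3, 4, 5), 1)      # cluster responses, 1 voxel
  b <- matrix(c(1, 2, 3), 1)      # random-object responses
  atlas <- structure(list(maps = rbind(x = 4),
                          exemplar_responses = list(x = a),
                          exemplar_counts = c(x = 3L), categories = "x"),
                     class = "category_atlas")
  mask <- cluster_specific_region(atlas, cluster_labels = 1, cluster_id = 1,
                                  random_responses = b, alpha = 0.05)
  tt <- t.test(c(3, 4, 5), c(1, 2, 3), var.equal = TRUE)
  expect_equal(unname(attr(mask, "t")[1]), unname(tt$statistic))

  # null: no planted difference -> empty mask in >= 95% of replicates
  empty <- withr::with_seed(3, replicate(60, {
    nv <- 40
    a0 <- matrix(rnorm(nv * 30), nv)
    b0 <- matrix(rnorm(nv * 50), nv)
    at <- structure(list(maps = matrix(rowMeans(a0), 1),
                         exemplar_responses = list(x = a0),
                         exemplar_counts = c(x = 30L), categories = "x"),
                    class = "category_atlas")
    !any(cluster_specific_region(at, 1, 1, b0, alpha = 0.01))
  }))
  expect_gte(mean(empty), 0.95)

  # planted recovery: voxels with elevated cluster response are found
  withr::with_seed(4, {
    nv <- 60
    hot <- 1:20
    a1 <- matrix(rnorm(nv * 40), nv)
    a1[hot, ] <- a1[hot, ] + 1
    b1 <- matrix(rnorm(nv * 200), nv)
  })
  at1 <- structure(list(maps = matrix(rowMeans(a1), 1),
                        exemplar_responses = list(x = a1),
                        exemplar_counts = c(x = 40L), categories = "x"),
                   class = "category_atlas")
  m1 <- cluster_specific_region(at1, 1, 1, b1, alpha = 0.01)
  expect_gt(mean(m1[hot]), 0.9)
  expect_lt(mean(m1[-hot]), 0.1)
  expect_error(cluster_specific_region(at1, 1, 1, b1[, 1, drop = FALSE]),
               "random objects")
})

test_that("sub-clustering recovers planted subgroups in the fixture world", {
  w <- test_world()
  clus <- cluster_categories(similarity_matrix(w$atlas, w$mask),
                             k_range = 2:6, seed = 5)
  groups <- w$hier$table$group
  expect_equal(adjusted_rand(clus$labels, as.integer(factor(groups))), 1)

  bio <- which(groups == "biological_objects")
  bio_cluster <- unique(clus$labels[bio])
  rand_ex <- make_random_exemplars(w$gen, 400, seed = 77)
  rand_resp <- category_map(w$model, w$bases, rand_ex, w$standardizers)$responses
  region <- cluster_specific_region(w$atlas, clus$labels, bio_cluster,
                                    rand_resp, alpha = 0.01)
  expect_gt(sum(region), 5)
  sub <- subcluster(w$atlas, region, bio, k_range = 2:6, seed = 6)
  subgroups <- w$hier$table$subgroup[bio]
  expect_identical(sub$k, 4L)
  expect_equal(adjusted_rand(sub$labels, as.integer(factor(subgroups))), 1)

  # with the full predictable mask, sub-clustering of the cluster's
  # categories stays consistent with the coarse partition restricted there
  sub_full <- subcluster(w$atlas, w$mask, bio, k_range = 2:6, seed = 6)
  expect_lte(sub_full$k, 4L)
  expect_error(subcluster(w$atlas, rep(FALSE, length(w$mask)), bio), "empty")
  expect_error(subcluster(w$atlas, w$mask, bio[1:2]), "3 categories")
})
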