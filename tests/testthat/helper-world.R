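# Shared fixtures, built once per test run and memoised.

.world_cache <- new.env(parent = emptyenv())

# Small but fully planted synthetic world run through the whole encoding
# chain; used by the category-representation, clustering and layer tests.
test_world <- function() {
  if (!is.null(.world_cache$world)) return(.world_cache$world)
  gen <- generator_config(n_voxels = 400, units_per_layer = 32,
                          n_train_sessions = 18, n_test_sessions = 2,
                          session_length = 120, seed = 42)
  hier <- category_hierarchy(exemplars_per_category_mean = 24)
  feats <- make_layered_features(gen, hier)
  truth <- make_voxel_population(gen, hier)
  resp <- simulate_responses(feats, truth, gen)
  pre <- prepare_train_test(feats, hrf_kernel(gen$time_step), gen$tr)
  halves <- pre
  bases <- fit_pca(halves$train)
  design_train <- transform_features(halves$train, bases)
  design_test <- transform_features(halves$test, bases)
  obs_train <- preprocess_responses(resp$train)
  obs_test <- preprocess_responses(resp$test)
  model <- fit_ridge(design_train, obs_train)
  report <- evaluate_encoding(model, design_test, obs_test,
                              test_repeats = resp$test, n_perm = 200,
                              n_sim = 100, seed = 7)
  exemplars <- make_category_exemplars(gen, hier)
  std <- pre$standardizers
  atlas <- build_category_atlas(model, bases, exemplars, std)
  mask <- predictable_mask(report)
  .world_cache$world <- list(
    gen = gen, hier = hier, feats = feats, truth = truth, resp = resp,
    train_lf = halves$train, test_lf = halves$test,
    bases = bases, design_train = design_train, design_test = design_test,
    obs_train = obs_train, obs_test = obs_test, model = model,
    report = report, exemplars = exemplars, standardizers = std,
    atlas = atlas, mask = mask)
  .world_cache$world
}

# Tiny layered series with known content for pipeline unit tests.
toy_series <- function(n = 60, p = c(4, 3), time_step = 1, sessions = 2,
                       seed = 1) {
  withr::with_seed(seed, {
    layers <- lapply(p, function(pp) matrix(rnorm(n * pp), n, pp))
    layered_features(layers, time_step = time_step,
                     sessions = rep(seq_len(sessions), each = n / sessions),
                     session_role = stats::setNames(
                       rep(c("train", "test"), length.out = sessions),
                       seq_len(sessions)))
  })
}

# Independent brute-force signed modularity, written term-by-term from the
# definition (p_ij = S_ij / S_tot etc.); deliberately naive.
brute_modularity <- function(S, labels) {
  n <- nrow(S)
  part <- function(w) {
    tot <- 0
    for (i in 1:n) for (j in 1:n) if (i != j) tot <- tot + w[i, j]
    if (tot <= 0) return(0)
    q <- 0
    row_s <- sapply(1:n, function(i) sum(w[i, -i]) / tot)
    col_s <- sapply(1:n, function(j) sum(w[-j, j]) / tot)
    for (i in 1:n) for (j in 1:n) {
      if (labels[i] != labels[j]) next
      p_ij <- if (i == j) 0 else w[i, j] / tot
      q <- q + p_ij - row_s[i] * col_s[j]
    }
    q
  }
  off <- S; diag(off) <- 0
  wp <- pmax(off, 0); wm <- pmax(-off, 0)
  sp <- sum(wp); sm <- sum(wm)
  if (sp + sm == 0) return(0)
  sp / (sp + sm) * part(wp) - sm / (sp + sm) * part(wm)
}

# All set partitions of 1..n (restricted growth strings), optionally capped
# at a maximum number of blocks.
all_partitions <- function(n, max_blocks = n) {
  out <- list()
  rec <- function(assign, next_block) {
    i <- length(assign) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- assign; return() }
    for (b in seq_len(min(next_block, max_blocks)))
      rec(c(assign, b), next_block + (b == next_block))
  }
  rec(integer(0), 1L)
  out
}

# Adjusted Rand index between two labelings (contingency-table formula).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Random symmetric similarity-like matrix with unit diagonal.
random_similarity <- function(n, sd = 0.3, seed = 1) {
  withr::with_seed(seed, {
    s <- matrix(0, n, n)
    s[upper.tri(s)] <- pmax(pmin(rnorm(n * (n - 1) / 2, sd = sd), 0.99), -0.99)
    s <- s + t(s)
    diag(s) <- 1
    s
  })
}

as_network <- function(S) {
  off <- S; diag(off) <- 0
  structure(list(S = S, S_plus = pmax(off, 0), S_minus = pmax(-off, 0),
                 zero_variance = rep(FALSE, nrow(S)), n_voxels = NA),
            class = "similarity_network")
}
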