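#' Default end-to-end pipeline configuration
#'
#' Desk-scale settings reproducing the full analysis chain on synthetic
#' data. Every threshold of the analysis is surfaced as a named key with
#' its standard value as default: variance retention 0.99, predictable-voxel
#' q < 0.01 and r > 0.2, region alpha 0.01.
#'
#' @param out_dir Output directory for stage artifacts.
#' @param generator Named list of [generator_config()] overrides.
#' @param hierarchy Named list of [category_hierarchy()] overrides.
#' @param thresholds Named list: `variance`, `q`, `r`, `alpha`.
#' @param permutations Named list: `block`, `modularity`, `semantic`
#'   (desk-scale counts; full-scale values reachable by config).
#' @param k_range Candidate cluster counts.
#' @param n_random Number of random objects for cluster-specific regions.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("cortcat_run_"),
                            generator = list(), hierarchy = list(),
                            thresholds = list(), permutations = list(),
                            k_range = 2:8, n_random = 2000, seed = 1L) {
  thr <- utils::modifyList(list(variance = 0.99, q = 0.01, r = 0.2,
                                alpha = 0.01), thresholds)
  perm <- utils::modifyList(list(block = 1000, modularity = 10000,
                                 semantic = 10000), permutations)
  structure(list(out_dir = out_dir, generator = generator,
                 hierarchy = hierarchy, thresholds = thr,
                 permutations = perm, k_range = k_range,
                 n_random = n_random, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as JSON
#'
#' @param path JSON file path.
#' @return `read_pipeline_config` returns a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- pipeline_config(
    out_dir = raw$out_dir %||% tempfile("cortcat_run_"),
    generator = as.list(raw$generator), hierarchy = as.list(raw$hierarchy),
    thresholds = as.list(raw$thresholds),
    permutations = as.list(raw$permutations),
    k_range = if (length(raw$k_range)) raw$k_range else 2:8,
    n_random = raw$n_random %||% 2000, seed = raw$seed %||% 1L)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Validate a pipeline configuration
#'
#' Report-only check of every configuration invariant; never throws.
#'
#' @param config A `pipeline_config` (or path to a JSON config).
#' @return Data frame with columns `check`, `ok`, `message`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  checks <- list()
  add <- function(check, ok, message = "") {
    checks[[length(checks) + 1L]] <<- data.frame(check = check, ok = ok,
                                                 message = message,
                                                 stringsAsFactors = FALSE)
  }
  thr <- config$thresholds
  add("variance_threshold", is.numeric(thr$variance) && thr$variance > 0 &&
        thr$variance <= 1,
      if (!(is.numeric(thr$variance) && thr$variance > 0 && thr$variance <= 1))
        sprintf("variance threshold %s outside (0, 1]", thr$variance) else "")
  add("q_threshold", thr$q > 0 && thr$q < 1, "")
  add("r_threshold", thr$r >= -1 && thr$r <= 1, "")
  add("alpha", thr$alpha > 0 && thr$alpha < 1, "")
  gen <- tryCatch(do.call(generator_config, config$generator),
                  error = function(e) e)
  add("generator", !inherits(gen, "error"),
      if (inherits(gen, "error")) conditionMessage(gen) else "")
  hier <- tryCatch(do.call(category_hierarchy, config$hierarchy),
                   error = function(e) e)
  add("hierarchy", !inherits(hier, "error"),
      if (inherits(hier, "error")) conditionMessage(hier) else "")
  if (!inherits(hier, "error")) {
    n_cat <- nrow(hier$table)
    ok <- all(config$k_range >= 2) && max(config$k_range) <= n_cat - 1L
    add("k_range", ok,
        if (!ok) sprintf("k_range must lie in 2..%d (categories - 1); affects the clustering stage",
                         n_cat - 1L) else "")
  }
  add("n_random", .is_count(config$n_random) && config$n_random >= 2, "")
  add("permutations", all(unlist(config$permutations) >= 100), "")
  do.call(rbind, checks)
}

#' Run the full analysis chain on synthetic data
#'
#' Sequences the stages synth -> features -> encode -> catmap -> cluster ->
#' semantics -> layers. Each stage writes its artifacts under
#' `config$out_dir` and records seeds, wall-clock time and output checksums
#' in a run manifest. With `resume = TRUE`, stages whose outputs already
#' exist are skipped.
#'
#' @param config A [pipeline_config()].
#' @param resume Skip stages whose cached stage file exists.
#' @return Invisibly, a list with the stage results and the `manifest` data
#'   frame.
#' @export
run_pipeline <- function(config = pipeline_config(), resume = FALSE) {
  val <- validate_config(config)
  if (!all(val$ok))
    .stopf("invalid config: %s",
           paste(val$check[!val$ok], collapse = ", "))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  gen <- do.call(generator_config, config$generator)
  hier <- do.call(category_hierarchy, config$hierarchy)
  state <- new.env(parent = emptyenv())
  manifest <- list()
  stage <- function(name, outputs, fun) {
    cache <- file.path(config$out_dir, paste0("stage_", name, ".rds"))
    t0 <- proc.time()[["elapsed"]]
    if (resume && file.exists(cache) &&
        all(file.exists(file.path(config$out_dir, outputs)))) {
      assign(name, readRDS(cache), envir = state)
      skipped <- TRUE
    } else {
      res <- tryCatch(fun(), error = function(e)
        .stopf("stage '%s' failed: %s", name, conditionMessage(e)))
      assign(name, res, envir = state)
      saveRDS(res, cache)
      skipped <- FALSE
    }
    files <- file.path(config$out_dir, outputs)
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = name, skipped = skipped,
      seconds = round(proc.time()[["elapsed"]] - t0, 3),
      outputs = paste(outputs, collapse = ";"),
      checksum = paste(unname(tools::md5sum(files[file.exists(files)])),
                       collapse = ";"),
      seed = gen$seed, stringsAsFactors = FALSE)
  }

  stage("synth", c("features.json", "taxonomy.tsv", "label_vectors.tsv"), function() {
    feats <- make_layered_features(gen, hier)
    truth <- make_voxel_population(gen)
    resp <- simulate_responses(feats, truth, gen)
    exemplars <- make_category_exemplars(gen, hier)
    tax <- make_toy_taxonomy(hier)
    vecs <- make_label_vectors(hier, seed = gen$seed + 7011L)
    write_layered_features(feats, config$out_dir, "features")
    write_taxonomy(tax, file.path(config$out_dir, "taxonomy.tsv"))
    write_label_vectors(vecs, file.path(config$out_dir, "label_vectors.tsv"))
    list(features = feats, truth = truth, responses = resp,
         exemplars = exemplars, taxonomy = tax, vectors = vecs)
  })
  synth <- get("synth", envir = state)

  stage("features", "design_train.json", function() {
    kern <- hrf_kernel(gen$time_step)
    pre <- prepare_train_test(synth$features, kern, gen$tr)
    std <- pre$standardizers
    train_lf <- pre$train
    test_lf <- pre$test
    bases <- fit_pca(train_lf, config$thresholds$variance)
    design_train <- transform_features(train_lf, bases)
    design_test <- transform_features(test_lf, bases)
    write_matrix_tsv(design_train$matrix, file.path(config$out_dir, "design_train.tsv"))
    jsonlite::write_json(list(kept = bases$layer_kept, k = bases$cross_kept,
                              threshold = bases$variance_threshold),
                         file.path(config$out_dir, "design_train.json"),
                         auto_unbox = TRUE, digits = NA)
    list(bases = bases, standardizers = std, train = design_train,
         test = design_test, test_features = test_lf)
  })
  feats <- get("features", envir = state)

  stage("encode", "accuracy.tsv", function() {
    obs_train <- preprocess_responses(synth$responses$train)
    obs_test <- preprocess_responses(synth$responses$test)
    model <- fit_ridge(feats$train, obs_train)
    report <- evaluate_encoding(model, feats$test, obs_test,
                                test_repeats = synth$responses$test,
                                n_perm = config$permutations$block,
                                n_sim = 200, seed = gen$seed + 8011L)
    r2 <- layer_explained_variance(model, feats$bases, feats$test_features, obs_test)
    assign_res <- assign_layer(r2)
    utils::write.table(
      data.frame(voxel = seq_along(report$r), r = report$r, p = report$p,
                 q = report$q, ceiling = report$ceiling,
                 r_normalized = report$r_normalized,
                 assigned_layer = assign_res$layer),
      file.path(config$out_dir, "accuracy.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    list(model = model, report = report, layer_r2 = r2, assigned = assign_res)
  })
  enc <- get("encode", envir = state)

  stage("catmap", "category_maps.tsv", function() {
    atlas <- build_category_atlas(enc$model, feats$bases, synth$exemplars,
                                  feats$standardizers)
    sel <- category_dprime(atlas)
    write_matrix_tsv(atlas$maps, file.path(config$out_dir, "category_maps.tsv"))
    write_matrix_tsv(sel$dprime_by_category,
                     file.path(config$out_dir, "dprime.tsv"))
    list(atlas = atlas, selectivity = sel)
  })
  cat_res <- get("catmap", envir = state)

  stage("cluster", "clustering.json", function() {
    mask <- predictable_mask(enc$report, config$thresholds$q, config$thresholds$r)
    net <- similarity_matrix(cat_res$atlas, mask)
    clus <- cluster_categories(net, k_range = config$k_range,
                               seed = gen$seed + 9011L)
    ptest <- modularity_permutation_test(net, clus$labels,
                                         n_perm = config$permutations$modularity,
                                         seed = gen$seed + 9111L)
    write_matrix_tsv(net$S, file.path(config$out_dir, "similarity.tsv"))
    write_clustering(clus, file.path(config$out_dir, "clustering.json"))
    list(mask = mask, network = net, clustering = clus, p_perm = ptest$p)
  })
  clus_res <- get("cluster", envir = state)

  stage("semantics", "semantics.json", function() {
    labels <- cat_res$atlas$categories
    sem_lch <- semantic_matrix(labels, "lch", taxonomy = synth$taxonomy)
    sem_cos <- semantic_matrix(labels, "cosine", vectors = synth$vectors)
    res <- lapply(list(lch = sem_lch, cosine = sem_cos), function(sem)
      representational_semantic_correlation(clus_res$network, sem,
                                            n_perm = config$permutations$semantic,
                                            seed = gen$seed + 10011L))
    jsonlite::write_json(
      lapply(res, function(x) list(r = x$r, p = x$p, n_perm = x$n_perm)),
      file.path(config$out_dir, "semantics.json"), auto_unbox = TRUE, digits = NA)
    list(matrices = list(lch = sem_lch, cosine = sem_cos), correlations = res)
  })
  sem_res <- get("semantics", envir = state)

  stage("layers", "layer_profile.tsv", function() {
    prof <- layer_profile(enc$model, feats$bases, synth$exemplars,
                          feats$standardizers, clus_res$mask,
                          clus_res$clustering$labels,
                          semantics = sem_res$matrices,
                          n_perm = min(config$permutations$semantic, 1000),
                          seed = gen$seed + 11011L)
    utils::write.table(prof$table, file.path(config$out_dir, "layer_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    prof
  })

  manifest <- do.call(rbind, manifest)
  utils::write.table(manifest, file.path(config$out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(synth = synth, features = feats, encode = enc,
                 catmap = cat_res, cluster = clus_res, semantics = sem_res,
                 layers = get("layers", envir = state), manifest = manifest))
}
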