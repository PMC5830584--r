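# Plain-text readers/writers for the pipeline's artifacts. Matrices travel
# as TSV with a JSON sidecar recording shapes and structure, taxonomies as
# child<TAB>parent edge lists, label vectors as label-indexed tables.

#' Write / read a numeric matrix as TSV
#'
#' @param x Numeric matrix.
#' @param path Output path.
#' @return `read_matrix_tsv` returns a numeric matrix (row names restored
#'   when present).
#' @export
write_matrix_tsv <- function(x, path) {
  df <- as.data.frame(x)
  if (!is.null(rownames(x))) df <- cbind(.label = rownames(x), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (".label" %in% names(df)) {
    rn <- df$.label
    df$.label <- NULL
    m <- as.matrix(df)
    rownames(m) <- rn
  } else m <- as.matrix(df)
  m
}

#' Write / read a layered feature series
#'
#' One TSV per layer plus a JSON sidecar with shapes, time step and session
#' structure.
#'
#' @param x A [layered_features()].
#' @param dir Output directory (created if needed).
#' @param name Artifact base name.
#' @return `read_layered_features` returns a `layered_features`.
#' @export
write_layered_features <- function(x, dir, name) {
  stopifnot(inherits(x, "layered_features"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("%s_layer%02d.tsv", name, seq_along(x$layers))
  for (l in seq_along(x$layers))
    write_matrix_tsv(x$layers[[l]], file.path(dir, files[l]))
  side <- list(name = name, n_layers = length(x$layers),
               units = vapply(x$layers, ncol, integer(1)),
               n_rows = nrow(x$layers[[1]]), time_step = x$time_step,
               sessions = x$sessions, session_role = as.list(x$session_role),
               files = files)
  jsonlite::write_json(side, file.path(dir, paste0(name, ".json")),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(file.path(dir, paste0(name, ".json")))
}

#' @rdname write_layered_features
#' @param sidecar Path to the JSON sidecar written by
#'   `write_layered_features`.
#' @export
read_layered_features <- function(sidecar) {
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  layers <- lapply(file.path(dirname(sidecar), side$files), read_matrix_tsv)
  role <- if (length(side$session_role)) unlist(side$session_role) else NULL
  layered_features(layers, time_step = side$time_step,
                   sessions = side$sessions, session_role = role)
}

#' Write / read voxel responses
#'
#' Values as TSV (voxel x time) plus a JSON sidecar with session ids and TR.
#'
#' @param x A [voxel_responses()]; the repeats array, if any, is not
#'   serialized (plain-text exchange carries the repeat-averaged values).
#' @param dir,name Output location.
#' @return `read_voxel_responses` returns a `voxel_responses`.
#' @export
write_voxel_responses <- function(x, dir, name) {
  stopifnot(inherits(x, "voxel_responses"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(x$values, file.path(dir, paste0(name, ".tsv")))
  jsonlite::write_json(list(name = name, sessions = x$sessions, tr = x$tr,
                            file = paste0(name, ".tsv")),
                       file.path(dir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(file.path(dir, paste0(name, ".json")))
}

#' @rdname write_voxel_responses
#' @param sidecar Sidecar path.
#' @export
read_voxel_responses <- function(sidecar) {
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  voxel_responses(read_matrix_tsv(file.path(dirname(sidecar), side$file)),
                  sessions = side$sessions, tr = side$tr)
}

#' Write / read a taxonomy as a child<TAB>parent edge list
#'
#' @param tax A [taxonomy()].
#' @param path Output path.
#' @return `read_taxonomy` returns a `taxonomy`.
#' @export
write_taxonomy <- function(tax, path) {
  stopifnot(inherits(tax, "taxonomy"))
  utils::write.table(tax$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_taxonomy
#' @export
read_taxonomy <- function(path) {
  edges <- utils::read.delim(path, header = FALSE,
                             col.names = c("child", "parent"))
  taxonomy(edges)
}

#' Write / read a label-vector table
#'
#' @param vectors Label-indexed matrix.
#' @param path Output path.
#' @return `read_label_vectors` returns the matrix.
#' @export
write_label_vectors <- function(vectors, path) write_matrix_tsv(vectors, path)

#' @rdname write_label_vectors
#' @export
read_label_vectors <- function(path) read_matrix_tsv(path)

#' Write a clustering result as JSON
#'
#' @param x A `clustering_result`.
#' @param path Output path.
#' @export
write_clustering <- function(x, path) {
  stopifnot(inherits(x, "clustering_result"))
  jsonlite::write_json(list(k = x$k, labels = x$labels, Q = x$Q,
                            Q_plus = x$Q_plus, Q_minus = x$Q_minus,
                            k_scan = x$k_scan, unstable = x$unstable),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
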