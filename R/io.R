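#' Write a dataset to CSV with a regenerating spec sidecar
#'
#' The CSV holds columns `x1..xp` and `label`; when a task spec is
#' supplied, a JSON sidecar (`<prefix>_spec.json`) stores every spec field
#' including the seed, so the dataset is exactly regenerable.
#'
#' @param dataset A [labeled_dataset()].
#' @param prefix File path prefix (no extension).
#' @param spec Optional [build_task_spec()] object to serialise alongside.
#' @return Invisibly, the CSV path.
#' @export
write_dataset <- function(dataset, prefix, spec = NULL) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  df <- data.frame(dataset$features, label = dataset$labels,
                   check.names = FALSE)
  csv <- paste0(prefix, ".csv")
  write.csv(df, csv, row.names = FALSE)
  if (!is.null(spec)) {
    jsonlite::write_json(
      list(K = spec$K,
           center_positions = unname(spec$center_positions),
           center_classes = spec$center_classes,
           cluster_sigma = spec$cluster_sigma,
           label_noise_rate = spec$label_noise_rate,
           n_irrelevant = spec$n_irrelevant,
           relevant_range = unname(spec$relevant_range),
           extent = spec$extent,
           seed = spec$seed),
      paste0(prefix, "_spec.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(csv)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param prefix File path prefix used when writing.
#' @param role Role to assign to the loaded dataset.
#' @return List with `dataset` (a [labeled_dataset()]) and `spec` (a
#'   `mixture_task_spec`, or `NULL` if no sidecar exists).
#' @export
read_dataset <- function(prefix, role = "full") {
  df <- read.csv(paste0(prefix, ".csv"), check.names = FALSE)
  feats <- as.matrix(df[setdiff(names(df), "label")])
  spec <- NULL
  sidecar <- paste0(prefix, "_spec.json")
  if (file.exists(sidecar)) {
    s <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    rr <- matrix(as.numeric(s$relevant_range), nrow = 2L,
                 dimnames = list(c("lo", "hi"), c("x1", "x2")))
    spec <- structure(list(K = as.integer(s$K),
                           center_positions = matrix(
                             as.numeric(s$center_positions), ncol = 2L,
                             dimnames = list(NULL, c("x1", "x2"))),
                           center_classes = as.numeric(s$center_classes),
                           cluster_sigma = s$cluster_sigma,
                           label_noise_rate = s$label_noise_rate,
                           n_irrelevant = as.integer(s$n_irrelevant),
                           relevant_range = rr,
                           extent = as.numeric(s$extent),
                           seed = as.integer(s$seed)),
                      class = "mixture_task_spec")
  }
  ds <- labeled_dataset(feats, df$label, role = role,
                        relevant_range = if (!is.null(spec)) spec$relevant_range)
  list(dataset = ds, spec = spec)
}

#' Serialise a kernel layer to JSON
#'
#' Stores the centers (row-major), widths and the provenance record of
#' which regime and seed selected them -- the "selected samples" artifact
#' that can be overlaid on the input data.
#'
#' @param layer A [kernel_layer()].
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_kernel_layer <- function(layer, path) {
  stopifnot(inherits(layer, "kernel_layer"))
  jsonlite::write_json(
    list(centers = unname(layer$centers), widths = layer$widths,
         provenance = layer$provenance),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Dump a center selection with coordinates and diagnostics to JSON
#'
#' One file per (condition, regime, seed): center indices, center
#' coordinates, hyperparameters and regime diagnostics -- sufficient to
#' regenerate selected-centers-over-data overlays.
#'
#' @param selection A `center_selection` from [select_centers()].
#' @param train The training [labeled_dataset()] the indices refer to.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
dump_center_selection <- function(selection, train, path) {
  stopifnot(inherits(selection, "center_selection"))
  idx <- selection$center_indices
  coords <- if (is.list(idx)) lapply(idx, function(i)
    unname(train$features[i, , drop = FALSE])) else
      unname(train$features[idx, , drop = FALSE])
  diag <- selection$diagnostics
  diag$log <- NULL # the streaming log can be large; keep the dump compact
  jsonlite::write_json(
    list(regime = unclass(selection$regime), center_indices = idx,
         center_coordinates = coords, diagnostics = diag),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
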