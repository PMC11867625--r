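# Delimited matrix IO. Values are printed with %.17g so a write/read round
# trip reproduces every double bit-exactly.
write_matrix <- function(m, path) {
  m <- as.matrix(m)
  lines <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

read_matrix <- function(path) {
  unname(as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                     colClasses = "numeric")))
}

#' Write a synthetic dataset to disk
#'
#' Writes the maps, vertex areas, per-run vertex timeseries and latent
#' timeseries as tab-delimited text matrices, with a JSON sidecar holding the
#' dimensions, TR, run labels, configuration and planted ground truth. Values
#' round-trip bit-exactly through [read_dataset()]. The CIFTI-2 format is not
#' supported by this build; use the delimited format.
#'
#' @param dataset A `synth_dataset` from [simulate_dataset()].
#' @param path Output directory (created if needed).
#' @param format `"delimited"` (only supported value; `"cifti"` errors).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, format = c("delimited", "cifti")) {
  format <- match.arg(format)
  if (format == "cifti")
    stop("CIFTI-2 output is not supported by this build; use format = 'delimited'",
         call. = FALSE)
  stopifnot(inherits(dataset, "synth_dataset"))
  if (length(dataset$runs) == 0L) stop("dataset has no runs", call. = FALSE)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write_matrix(dataset$maps, file.path(path, "maps.tsv"))
  write_matrix(matrix(dataset$vertex_area, nrow = 1), file.path(path, "areas.tsv"))
  run_labels <- sprintf("run-%02d", seq_along(dataset$runs))
  for (r in seq_along(dataset$runs)) {
    write_matrix(dataset$runs[[r]], file.path(path, paste0(run_labels[r], ".tsv")))
    write_matrix(dataset$truth$latent_series[[r]],
                 file.path(path, paste0("latents-", run_labels[r], ".tsv")))
  }
  cfg <- dataset$config
  sidecar <- list(
    n_vertices = cfg$n_vertices, n_timepoints = cfg$n_timepoints,
    n_modes = cfg$n_modes, n_runs = length(dataset$runs),
    tr_seconds = cfg$tr_seconds, run_labels = run_labels,
    config = unclass(cfg),
    truth = list(mechanism = dataset$truth$mechanism,
                 membership = dataset$truth$membership,
                 switch_schedule = dataset$truth$switch_schedule))
  jsonlite::write_json(sidecar, file.path(path, "dataset.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a synthetic dataset written by [write_dataset()]
#'
#' @param path Directory written by [write_dataset()].
#' @return A `synth_dataset` equal (bit-exactly in all matrices) to the one
#'   written.
#' @export
read_dataset <- function(path) {
  side_path <- file.path(path, "dataset.json")
  if (!file.exists(side_path))
    stop(sprintf("no dataset sidecar at '%s'", side_path), call. = FALSE)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  cfg <- do.call(synth_config,
                 side$config[setdiff(names(side$config), character(0))])
  maps <- read_matrix(file.path(path, "maps.tsv"))
  rownames(maps) <- paste0("mode", seq_len(nrow(maps)))
  runs <- lapply(side$run_labels,
                 function(lb) read_matrix(file.path(path, paste0(lb, ".tsv"))))
  latents <- lapply(side$run_labels, function(lb) {
    m <- read_matrix(file.path(path, paste0("latents-", lb, ".tsv")))
    rownames(m) <- paste0("mode", seq_len(nrow(m)))
    m
  })
  mem <- side$truth$membership
  membership <- list(
    unique_regions = lapply(mem$unique_regions, as.integer),
    overlap = as.integer(mem$overlap),
    overlap_pair = as.integer(mem$overlap_pair),
    generator_net = if (is.null(mem$generator_net)) NULL
                    else as.integer(mem$generator_net))
  sched <- side$truth$switch_schedule
  structure(list(
    config = cfg, maps = maps,
    vertex_area = as.numeric(read_matrix(file.path(path, "areas.tsv"))),
    runs = runs,
    truth = list(mechanism = side$truth$mechanism, membership = membership,
                 latent_series = latents,
                 switch_schedule = if (is.null(sched)) NULL else as.integer(sched))
  ), class = "synth_dataset")
}

#' Load a mode set and run data from delimited files
#'
#' Reader for users bringing their own decomposition as plain text: a `K x V`
#' map matrix, optional `V x T` vertex timeseries per run, optional vertex
#' areas, and an optional JSON sidecar carrying the TR. Shapes are validated
#' (`V` must agree everywhere).
#'
#' @param maps_path Path to the tab-delimited `K x V` map matrix.
#' @param series_paths Character vector of paths to `V x T` run matrices.
#' @param areas_path Optional path to the vertex areas (one row or column).
#' @param sidecar_path Optional path to a JSON file with a `tr_seconds` field.
#' @return List with `modes` (a [mode_set()]), `runs`, `vertex_area`, and
#'   `tr_seconds` (`NA` if no sidecar).
#' @export
load_modeset <- function(maps_path, series_paths = character(0),
                         areas_path = NULL, sidecar_path = NULL) {
  maps <- read_matrix(maps_path)
  V <- ncol(maps)
  runs <- lapply(series_paths, read_matrix)
  for (i in seq_along(runs))
    if (nrow(runs[[i]]) != V)
      stop(sprintf("vertex mismatch: maps are %d x %d but '%s' is %d x %d",
                   nrow(maps), V, series_paths[i],
                   nrow(runs[[i]]), ncol(runs[[i]])), call. = FALSE)
  area <- if (!is.null(areas_path)) as.numeric(read_matrix(areas_path)) else rep(1, V)
  if (length(area) != V)
    stop(sprintf("area vector length %d does not match V = %d",
                 length(area), V), call. = FALSE)
  tr <- NA_real_
  if (!is.null(sidecar_path)) {
    side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    if (!is.null(side$tr_seconds)) tr <- as.numeric(side$tr_seconds)
  }
  list(modes = mode_set(maps), runs = runs, vertex_area = area,
       tr_seconds = tr)
}
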