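#' Threshold-free spatial overlap matrix
#'
#' `K x K` matrix of Pearson correlations across vertices between all pairs of
#' weighted mode maps — a threshold-free summary of overlapping network
#' organization. Fisher-z values (`atanh`, with `|r|` clipped at `1 - 1e-12`)
#' are carried alongside for averaging.
#'
#' @param maps `K x V` matrix (or `mode_set`) of signed map weights.
#' @return Object of class `overlap_matrix`: list with `values` (symmetric,
#'   unit diagonal), `z_values`, and `n_vertices_used`.
#' @export
overlap_matrix <- function(maps) {
  maps <- as_maps(maps)
  if (nrow(maps) < 2L) stop("need at least 2 maps", call. = FALSE)
  r <- spatial_corr_matrix(maps, maps)
  r <- (r + t(r)) / 2          # exact symmetry against float asymmetry
  diag(r) <- 1
  structure(list(values = r, z_values = fisher_z(r),
                 n_vertices_used = ncol(maps)),
            class = "overlap_matrix")
}

#' @export
print.overlap_matrix <- function(x, ...) {
  K <- nrow(x$values)
  off <- x$values[lower.tri(x$values)]
  cat(sprintf("<overlap_matrix> K=%d over %d vertices; off-diagonal r: median %.3f, range [%.3f, %.3f]\n",
              K, x$n_vertices_used, stats::median(off), min(off), max(off)))
  invisible(x)
}

#' Tidy an overlap matrix into edge rows
#'
#' @param x An `overlap_matrix`.
#' @param ... Unused.
#' @return Tibble with one row per lower-triangle edge: `mode_i`, `mode_j`,
#'   `r`, `z`.
#' @export
tidy.overlap_matrix <- function(x, ...) {
  K <- nrow(x$values)
  idx <- which(lower.tri(x$values), arr.ind = TRUE)
  tibble::tibble(mode_i = idx[, 2], mode_j = idx[, 1],
                 r = x$values[idx], z = x$z_values[idx])
}

#' Group-average overlap matrices in Fisher-z space
#'
#' Correlations are z-transformed prior to averaging across individuals and
#' the mean is transformed back with `tanh`. Idempotent on identical inputs
#' and invariant to subject order.
#'
#' @param matrices List of `overlap_matrix` objects with equal `K`.
#' @return An `overlap_matrix` holding the group average.
#' @export
group_average_overlap <- function(matrices) {
  if (length(matrices) == 0L) stop("empty list of overlap matrices", call. = FALSE)
  stopifnot(all(vapply(matrices, inherits, TRUE, "overlap_matrix")))
  K <- nrow(matrices[[1]]$values)
  if (any(vapply(matrices, function(m) nrow(m$values), 1L) != K))
    stop("overlap matrices differ in K", call. = FALSE)
  zbar <- Reduce(`+`, lapply(matrices, `[[`, "z_values")) / length(matrices)
  r <- fisher_z_inv(zbar)
  diag(r) <- 1
  structure(list(values = r, z_values = fisher_z(r),
                 n_vertices_used = matrices[[1]]$n_vertices_used),
            class = "overlap_matrix")
}

#' Binarized, area-weighted overlap count map
#'
#' Binarizes each mode map at `threshold` (default 1; in the motivating data
#' an absolute weight of 1 sits at roughly the 96.5th weight percentile, a
#' conservative choice) and counts at each vertex how many modes exceed it.
#' Each vertex's indicator is multiplied by its cortical surface area so that
#' the total area covered by 2-, 3-, 4- and 5-plus-network overlap can be
#' reported. Negative weights never exceed a positive threshold, so they are
#' naturally excluded from counting.
#'
#' @param maps `K x V` matrix (or `mode_set`).
#' @param vertex_area Length-`V` positive vertex areas in mm^2 (default 1).
#' @param threshold Binarization threshold (default 1.0).
#' @return Object of class `overlap_count_map`: `counts` (length `V`),
#'   `area_weighted` (vertex area where the vertex overlaps at all, i.e.
#'   `count >= 2`), `threshold`, and `level_areas`, a tibble of total area at
#'   count levels 0, 1, 2, 3, 4 and `5+`.
#' @export
overlap_count_map <- function(maps, vertex_area = NULL, threshold = 1.0) {
  maps <- as_maps(maps)
  V <- ncol(maps)
  if (is.null(vertex_area)) vertex_area <- rep(1, V)
  if (length(vertex_area) != V || any(vertex_area <= 0))
    stop("`vertex_area` must be length V and positive", call. = FALSE)
  counts <- colSums(maps >= threshold)
  level <- ifelse(counts >= 5, "5+", as.character(counts))
  level_areas <- tibble::tibble(level = c("0", "1", "2", "3", "4", "5+")) |>
    dplyr::left_join(
      tibble::tibble(level = level, area = vertex_area) |>
        dplyr::group_by(.data$level) |>
        dplyr::summarise(area_mm2 = sum(.data$area), n_vertices = dplyr::n()),
      by = "level") |>
    tidyr::replace_na(list(area_mm2 = 0, n_vertices = 0L))
  structure(list(counts = as.integer(counts),
                 area_weighted = ifelse(counts >= 2, vertex_area, 0),
                 threshold = threshold, level_areas = level_areas),
            class = "overlap_count_map")
}

#' @export
print.overlap_count_map <- function(x, ...) {
  cat(sprintf("<overlap_count_map> threshold %.2f; overlap (count >= 2) area %.1f mm^2 over %d vertices\n",
              x$threshold, sum(x$area_weighted), sum(x$counts >= 2)))
  print(x$level_areas)
  invisible(x)
}
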