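#' Threshold configuration for two-network vertex assignment
#'
#' Holds the network-weight threshold and the exclusion threshold applied to
#' the summed weight of all remaining modes, plus the 3 x 3 robustness grid of
#' weight thresholds `{0.75, 1, 1.25}` crossed with exclusion thresholds
#' `{0.02, 0.1, 0.5}`.
#'
#' @param net_weight_thr Weight a vertex needs on a network to count as
#'   belonging to it (default 1.0).
#' @param excl_thr A vertex is excluded when the other network (for unique
#'   labels) or the summed weight of the remaining modes reaches this value
#'   (default 0.1).
#' @param grid Data frame with columns `net_weight_thr`, `excl_thr`; defaults
#'   to the 9-configuration robustness grid.
#' @param positive_part_sum Should the exclusion sum over the remaining modes
#'   use only positive weights (default `TRUE`; negative map weights do not
#'   count toward network overlap, and letting them cancel positive weights
#'   would mask real contributions)? Set `FALSE` for a signed sum.
#' @return Object of class `threshold_config`.
#' @export
threshold_config <- function(net_weight_thr = 1.0, excl_thr = 0.1,
                             grid = NULL, positive_part_sum = TRUE) {
  stopifnot_scalar(net_weight_thr, "net_weight_thr")
  stopifnot_scalar(excl_thr, "excl_thr")
  if (net_weight_thr <= excl_thr)
    stop("`net_weight_thr` must exceed `excl_thr`", call. = FALSE)
  if (is.null(grid))
    grid <- tidyr::expand_grid(net_weight_thr = c(0.75, 1, 1.25),
                               excl_thr = c(0.02, 0.1, 0.5))
  structure(list(net_weight_thr = net_weight_thr, excl_thr = excl_thr,
                 grid = tibble::as_tibble(grid),
                 positive_part_sum = isTRUE(positive_part_sum)),
            class = "threshold_config")
}

#' Number of unordered network pairs
#'
#' @param K Number of modes (at least 2).
#' @return `K * (K - 1) / 2`.
#' @export
#' @examples
#' count_pairs(12)  # 66
count_pairs <- function(K) {
  stopifnot_scalar(K, "K", integerish = TRUE)
  if (K < 2) stop("`K` must be at least 2", call. = FALSE)
  as.integer(K * (K - 1) / 2)
}

#' Assign vertices to unique / overlap / excluded labels for a network pair
#'
#' For the pair `(i, j)`: a vertex is uniquely associated with network 1 when
#' its weight on mode `i` reaches `net_weight_thr`, its weight on mode `j` is
#' below `excl_thr`, and the summed weight across the remaining `K - 2` modes
#' is below `excl_thr`; symmetrically for network 2. It belongs to the overlap
#' region when both pair weights reach `net_weight_thr` and the remaining-mode
#' sum stays below `excl_thr`. All other vertices are excluded. By default the
#' remaining-mode sum uses positive parts only (see [threshold_config()]).
#' Vertices with negative pair weights fail the threshold test naturally.
#'
#' @param maps `K x V` matrix (or `mode_set`).
#' @param pair Integer vector `(i, j)`, distinct modes.
#' @param cfg A [threshold_config()].
#' @return Object of class `pair_assignment`: `pair`, `labels` (length-`V`
#'   factor with levels `N1`, `N2`, `OVERLAP`, `EXCLUDED`), per-label `counts`,
#'   and the thresholds used.
#' @export
assign_vertices <- function(maps, pair, cfg = threshold_config()) {
  maps <- as_maps(maps)
  pair <- as.integer(pair)
  if (length(pair) != 2L || pair[1] == pair[2])
    stop("`pair` must be two distinct mode indices", call. = FALSE)
  K <- nrow(maps)
  if (any(pair < 1L) || any(pair > K))
    stop("`pair` out of range", call. = FALSE)
  wi <- maps[pair[1], ]; wj <- maps[pair[2], ]
  if (K > 2L) {
    rest <- maps[-pair, , drop = FALSE]
    if (cfg$positive_part_sum) rest <- pmax(rest, 0)
    other <- colSums(rest)
  } else {
    other <- rep(0, ncol(maps))
  }
  thr <- cfg$net_weight_thr; excl <- cfg$excl_thr
  ok_other <- other < excl
  lab <- rep("EXCLUDED", ncol(maps))
  lab[wi >= thr & wj < excl & ok_other] <- "N1"
  lab[wj >= thr & wi < excl & ok_other] <- "N2"
  lab[wi >= thr & wj >= thr & ok_other] <- "OVERLAP"
  labels <- factor(lab, levels = c("N1", "N2", "OVERLAP", "EXCLUDED"))
  structure(list(pair = pair, labels = labels,
                 counts = table(labels),
                 net_weight_thr = thr, excl_thr = excl),
            class = "pair_assignment")
}

#' @export
print.pair_assignment <- function(x, ...) {
  cat(sprintf("<pair_assignment> modes (%d, %d), thresholds (%.2f, %.2f): ",
              x$pair[1], x$pair[2], x$net_weight_thr, x$excl_thr))
  cat(paste(names(x$counts), as.integer(x$counts), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Select network pairs with robust overlap across a cohort
#'
#' A pair is retained when its overlap region contains at least `min_vertices`
#' vertices in at least `ceil(min_subject_fraction * S)` of the `S` subjects
#' (defaults: 25 vertices, half of the subjects).
#'
#' @param overlap_counts Data frame with columns `subject`, `pair` (any pair
#'   identifier), and `n_overlap` — one row per subject x pair, e.g. built
#'   from [assign_vertices()] counts.
#' @param min_vertices Minimum overlap-region size (default 25).
#' @param min_subject_fraction Minimum fraction of subjects (default 0.5).
#' @return Tibble per pair: `pair`, `n_qualifying`, `n_subjects`, `retained`.
#' @export
select_pairs <- function(overlap_counts, min_vertices = 25L,
                         min_subject_fraction = 0.5) {
  df <- tibble::as_tibble(overlap_counts)
  if (!all(c("subject", "pair", "n_overlap") %in% names(df)))
    stop("`overlap_counts` needs columns subject, pair, n_overlap", call. = FALSE)
  S <- dplyr::n_distinct(df$subject)
  need <- ceiling(min_subject_fraction * S)
  df |>
    dplyr::group_by(.data$pair) |>
    dplyr::summarise(n_qualifying = sum(.data$n_overlap >= min_vertices),
                     .groups = "drop") |>
    dplyr::mutate(n_subjects = S, retained = .data$n_qualifying >= need)
}

#' Extract standardized N1 / N2 / Overlap summary timeseries
#'
#' Averages the vertex timeseries within each label set and standardizes each
#' summary to mean 0, population sd 1 within the run. When the overlap region
#' (or either unique region) is empty, or an averaged series has zero
#' variance, a flagged empty result is returned so the run can be excluded
#' downstream rather than erroring.
#'
#' @param data `V x T` matrix of vertex timeseries for one run.
#' @param assignment A [assign_vertices()] result.
#' @return Object of class `summary_triple`: `n1`, `n2`, `o` (length-`T`
#'   standardized series, or `NULL` when flagged), `ok` (logical), `flag`
#'   (reason when not ok).
#' @export
extract_summary <- function(data, assignment) {
  stopifnot(inherits(assignment, "pair_assignment"))
  data <- as.matrix(data)
  if (nrow(data) != length(assignment$labels))
    stop(sprintf("data has %d vertices but assignment has %d",
                 nrow(data), length(assignment$labels)), call. = FALSE)
  sets <- split(seq_len(nrow(data)), assignment$labels)
  flagged <- function(reason)
    structure(list(n1 = NULL, n2 = NULL, o = NULL, ok = FALSE, flag = reason),
              class = "summary_triple")
  for (lbl in c("N1", "N2", "OVERLAP"))
    if (length(sets[[lbl]]) == 0L)
      return(flagged(paste0("empty ", lbl, " set")))
  avg <- lapply(sets[c("N1", "N2", "OVERLAP")],
                function(idx) colMeans(data[idx, , drop = FALSE]))
  if (any(vapply(avg, is_zero_var, TRUE)))
    return(flagged("zero-variance summary series"))
  structure(list(n1 = zscore(avg$N1), n2 = zscore(avg$N2),
                 o = zscore(avg$OVERLAP), ok = TRUE, flag = NA_character_),
            class = "summary_triple")
}

#' @export
print.summary_triple <- function(x, ...) {
  if (x$ok) cat(sprintf("<summary_triple> T=%d, standardized\n", length(x$o)))
  else cat(sprintf("<summary_triple> flagged: %s\n", x$flag))
  invisible(x)
}
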