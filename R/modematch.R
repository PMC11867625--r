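#' Construct a mode set
#'
#' Container for one network decomposition: `K` signed weighted spatial maps
#' over `V` vertices, optionally with per-run mode timeseries and a `K x K`
#' temporal netmat (partial-correlation edges).
#'
#' @param maps `K x V` numeric matrix of signed map weights.
#' @param run_series Optional list of `T x K` mode-timeseries matrices.
#' @param netmat Optional symmetric `K x K` matrix.
#' @param labels Optional mode names (default `mode1..modeK`).
#' @return Object of class `mode_set`.
#' @export
mode_set <- function(maps, run_series = NULL, netmat = NULL, labels = NULL) {
  maps <- as.matrix(maps)
  if (nrow(maps) < 2L) stop("a mode set needs at least 2 modes", call. = FALSE)
  if (!is.null(netmat)) {
    netmat <- as.matrix(netmat)
    if (!isTRUE(all.equal(netmat, t(netmat), tolerance = 1e-8)))
      stop("`netmat` must be symmetric", call. = FALSE)
    if (nrow(netmat) != nrow(maps))
      stop("`netmat` dimension must equal the number of modes", call. = FALSE)
  }
  if (!is.null(run_series)) {
    run_series <- lapply(run_series, as.matrix)
    if (any(vapply(run_series, ncol, 1L) != nrow(maps)))
      stop("each run_series matrix needs one column per mode", call. = FALSE)
  }
  if (is.null(labels)) labels <- paste0("mode", seq_len(nrow(maps)))
  structure(list(maps = maps, run_series = run_series, netmat = netmat,
                 labels = labels), class = "mode_set")
}

as_maps <- function(x) {
  if (inherits(x, "mode_set")) x$maps else as.matrix(x)
}

#' Network-to-network spatial correlation matrix
#'
#' Pearson correlation across vertices between every row of `mapsA` and every
#' row of `mapsB`. A zero-variance map yields correlations of 0 (with a
#' warning) rather than `NaN`, so the matrix stays finite for the assignment
#' solver.
#'
#' @param mapsA,mapsB `K x V` matrices (or `mode_set`s) over the same vertices.
#' @return `KA x KB` matrix of correlations in `[-1, 1]`.
#' @export
spatial_corr_matrix <- function(mapsA, mapsB) {
  A <- as_maps(mapsA); B <- as_maps(mapsB)
  if (ncol(A) != ncol(B))
    stop(sprintf("vertex counts differ: %d vs %d", ncol(A), ncol(B)),
         call. = FALSE)
  sdA <- apply(A, 1, pop_sd); sdB <- apply(B, 1, pop_sd)
  badA <- sdA < 1e-12; badB <- sdB < 1e-12
  if (any(badA) || any(badB))
    warning("zero-variance map(s); their correlations set to 0", call. = FALSE)
  A[badA, ] <- 0; B[badB, ] <- 0  # cor() would return NaN; handled below
  out <- suppressWarnings(stats::cor(t(A), t(B)))
  out[badA, ] <- 0; out[, badB] <- 0
  out
}

# O(K^3) shortest-augmenting-path Hungarian solver (minimizes total cost).
# Deterministic: columns are scanned in increasing index order, with strict
# inequalities, so tie resolution is platform-independent.
hungarian_solve <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n)        # row potentials
  v <- numeric(n + 1L)   # column potentials; index 1 is the virtual column 0
  p <- integer(n + 1L)   # p[j+1] = row currently matched to column j
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    used <- logical(n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0] - v[j + 1L]
          if (cur < minv[j]) { minv[j] <- cur; way[j + 1L] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L]] <- u[p[j + 1L]] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) assignment[p[j + 1L]] <- j
  assignment  # assignment[i] = column matched to row i
}

#' Match modes across decompositions with the Hungarian algorithm
#'
#' Solves the assignment problem on the network-to-network spatial correlation
#' matrix: finds the bijection between the rows of the reference set and the
#' rows of the target set that maximizes the total matched correlation
#' (equivalently, minimizes the trace of the permuted cost matrix `1 - r`).
#'
#' @param corr_matrix Square `K x K` matrix, e.g. from
#'   [spatial_corr_matrix()].
#' @return Object of class `mode_match`: list with `permutation` (entry `i` is
#'   the target mode matched to reference mode `i`), `matched_corrs`, the
#'   total matched correlation, and the input `corr_matrix`.
#' @export
#' @examples
#' hungarian_match(rbind(c(0.1, 0.9), c(0.8, 0.2)))$permutation
hungarian_match <- function(corr_matrix) {
  corr_matrix <- as.matrix(corr_matrix)
  if (nrow(corr_matrix) != ncol(corr_matrix))
    stop("`corr_matrix` must be square", call. = FALSE)
  if (!all(is.finite(corr_matrix)))
    stop("`corr_matrix` must be finite", call. = FALSE)
  perm <- hungarian_solve(1 - corr_matrix)
  matched <- corr_matrix[cbind(seq_len(nrow(corr_matrix)), perm)]
  structure(list(permutation = perm, matched_corrs = matched,
                 total = sum(matched), corr_matrix = corr_matrix),
            class = "mode_match")
}

#' @export
print.mode_match <- function(x, ...) {
  cat(sprintf("<mode_match> K=%d, total matched correlation %.3f\n",
              length(x$permutation), x$total))
  cat("permutation:", x$permutation, "\n")
  invisible(x)
}

#' Tidy a mode match
#'
#' @param x A `mode_match` from [hungarian_match()].
#' @param ... Unused.
#' @return Tibble with one row per reference mode: `reference`, `matched`,
#'   `correlation`.
#' @export
tidy.mode_match <- function(x, ...) {
  tibble::tibble(reference = seq_along(x$permutation),
                 matched = x$permutation,
                 correlation = x$matched_corrs)
}

#' Reliability-based mode selection
#'
#' A mode is retained when its median (across subjects) test-retest
#' correlation and its median group-individual correlation both reach the
#' threshold (default 0.7, a conventional lowest acceptable reliability).
#' `NaN`/`NA` entries are excluded from the medians; a mode whose column is
#' entirely missing is not selected (with a warning).
#'
#' @param trt_corrs,grp_corrs `S x K` matrices (subjects by modes) of
#'   test-retest and group-individual spatial correlations.
#' @param threshold Selection threshold applied to both medians (default 0.7).
#' @return Tibble with one row per mode: `mode`, `median_trt`, `median_grp`,
#'   `selected`.
#' @export
select_modes <- function(trt_corrs, grp_corrs, threshold = 0.7) {
  trt_corrs <- as.matrix(trt_corrs); grp_corrs <- as.matrix(grp_corrs)
  if (!identical(dim(trt_corrs), dim(grp_corrs)))
    stop("`trt_corrs` and `grp_corrs` must have identical dimensions",
         call. = FALSE)
  med <- function(m) apply(m, 2, function(col) {
    col <- col[is.finite(col)]
    if (length(col) == 0) NA_real_ else stats::median(col)
  })
  med_trt <- med(trt_corrs); med_grp <- med(grp_corrs)
  if (any(is.na(med_trt)) || any(is.na(med_grp)))
    warning("mode(s) with no finite correlations are not selected",
            call. = FALSE)
  selected <- !is.na(med_trt) & !is.na(med_grp) &
    med_trt >= threshold & med_grp >= threshold
  tibble::tibble(mode = seq_along(med_trt), median_trt = med_trt,
                 median_grp = med_grp, selected = selected)
}

#' Flag a mode as missing in an individual
#'
#' A subject's mode counts as missing when both its test-retest and its
#' subject-group correlation fall below the cutoff (default 0.2); a
#' non-finite correlation counts as below the cutoff.
#'
#' @param trt,grp Subject-level correlations (vectors recycle elementwise).
#' @param cutoff Missingness cutoff (default 0.2; strict `<`).
#' @return Logical vector.
#' @export
flag_missing <- function(trt, grp, cutoff = 0.2) {
  below <- function(x) !is.finite(x) | x < cutoff
  below(trt) & below(grp)
}

#' Stability measures between two matched mode sets
#'
#' Generic similarity used for test-retest, within-subject, twin and
#' between-subject comparisons: per-mode Pearson correlation of the spatial
#' maps across vertices (`which = "maps"`), or a single Pearson correlation
#' across the `K(K-1)/2` lower-triangle edges of the temporal netmats
#' (`"netmat_edges"`) or of the spatial overlap matrices (`"overlap_edges"`).
#'
#' @param setA,setB `mode_set`s (or bare `K x V` matrices) in matched order.
#' @param which One of `"maps"`, `"netmat_edges"`, `"overlap_edges"`.
#' @return Tibble: one row per mode for `"maps"` (`mode`, `r`), otherwise a
#'   single row (`measure`, `n_edges`, `r`).
#' @export
stability_measures <- function(setA, setB,
                               which = c("maps", "netmat_edges", "overlap_edges")) {
  which <- match.arg(which)
  if (which == "maps") {
    A <- as_maps(setA); B <- as_maps(setB)
    if (!identical(dim(A), dim(B))) stop("map shape mismatch", call. = FALSE)
    r <- vapply(seq_len(nrow(A)), function(k) safe_cor(A[k, ], B[k, ]), 1.0)
    return(tibble::tibble(mode = seq_len(nrow(A)), r = r))
  }
  get_mat <- function(x) {
    if (which == "netmat_edges") {
      if (!inherits(x, "mode_set") || is.null(x$netmat))
        stop("netmat_edges needs mode_sets carrying a netmat", call. = FALSE)
      x$netmat
    } else {
      overlap_matrix(as_maps(x))$values
    }
  }
  MA <- get_mat(setA); MB <- get_mat(setB)
  if (!identical(dim(MA), dim(MB))) stop("shape mismatch", call. = FALSE)
  lt <- lower.tri(MA)
  tibble::tibble(measure = which, n_edges = sum(lt),
                 r = safe_cor(MA[lt], MB[lt]))
}
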