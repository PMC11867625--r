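#' Block-switching semi-simulated overlap timeseries
#'
#' Rebuilds the overlap timeseries under the temporal-switching hypothesis:
#' the series starts with the first `block_len` timepoints of `n1`, then takes
#' the second `block_len` timepoints of `n2`, then the third block from `n1`,
#' and so on (each block keeps its own time indices); a trailing partial block
#' is included. The assembled series is then standardized.
#'
#' @param n1,n2 Length-`T` network summary timeseries.
#' @param block_len Block length in TRs.
#' @return Standardized length-`T` series.
#' @export
switch_blocks <- function(n1, n2, block_len) {
  check_same_length(n1, n2)
  stopifnot_scalar(block_len, "block_len", integerish = TRUE)
  T <- length(n1)
  if (block_len > T) {
    warning("block_len exceeds series length; single block equals n1",
            call. = FALSE)
    return(zscore(n1))
  }
  sched <- switch_schedule(T, block_len)
  zscore(ifelse(sched == 1L, n1, n2))
}

#' Max-switching semi-simulated overlap timeseries
#'
#' Per-TR switching: each timepoint takes whichever of the two standardized
#' network series is higher at that TR; the result is standardized.
#'
#' @inheritParams switch_blocks
#' @return Standardized length-`T` series.
#' @export
max_switch <- function(n1, n2) {
  check_same_length(n1, n2)
  zscore(pmax(zscore(n1), zscore(n2)))
}

#' Linear additive coupling semi-simulated overlap timeseries
#'
#' The sum of the two network series within each TR, standardized. A zero
#' variance sum (e.g. `n2 = -n1`) is degenerate and raises an error of class
#' `netoverlap_degenerate`; [semisim_bundle()] converts this into a flag.
#'
#' @inheritParams switch_blocks
#' @return Standardized length-`T` series.
#' @export
linear_add <- function(n1, n2) {
  check_same_length(n1, n2)
  s <- n1 + n2
  if (is_zero_var(s)) degenerate("linear_add: zero-variance sum")
  zscore(s)
}

#' Nonlinear multiplicative coupling semi-simulated overlap timeseries
#'
#' Elementwise product of the two standardized network series after clamping
#' each to a minimum of zero (avoiding negative values), then standardized.
#' An all-nonpositive input yields a zero-variance product and raises a
#' `netoverlap_degenerate` error.
#'
#' @inheritParams switch_blocks
#' @return Standardized length-`T` series.
#' @export
nonlin_mult <- function(n1, n2) {
  check_same_length(n1, n2)
  s <- pmax(zscore(n1), 0) * pmax(zscore(n2), 0)
  if (is_zero_var(s)) degenerate("nonlin_mult: zero-variance product")
  zscore(s)
}

#' Random spatial-mixture semi-simulated overlap timeseries
#'
#' Under the spatial mixing hypothesis the overlap region is a fine-grained
#' mixture of vertices individually belonging to one network. Half of the
#' overlap vertices (`ceiling(n_O / 2)`, network 1 taking the extra one) are
#' assigned the timeseries of a randomly chosen N1-unique vertex (with
#' replacement), the other half a randomly chosen N2-unique vertex; the
#' assigned series are averaged across all overlap vertices and standardized.
#' Unlike the summary-based generators this one repeats the averaging across
#' raw vertex timeseries. Uses the current RNG state; seed upstream for
#' reproducibility.
#'
#' @param data `V x T` vertex timeseries for the run.
#' @param assignment A [assign_vertices()] result.
#' @return Standardized length-`T` series.
#' @export
mix_random <- function(data, assignment) {
  sets <- donor_sets(assignment)
  n_o <- length(sets$overlap)
  take1 <- ceiling(n_o / 2); take2 <- n_o - take1
  d1 <- sets$n1[sample.int(length(sets$n1), take1, replace = TRUE)]
  d2 <- sets$n2[sample.int(length(sets$n2), take2, replace = TRUE)]
  s <- colMeans(as.matrix(data)[c(d1, d2), , drop = FALSE])
  if (is_zero_var(s)) degenerate("mix_random: zero-variance average")
  zscore(s)
}

#' Interdigitation spatial-mixture semi-simulated overlap timeseries
#'
#' Each overlap vertex is assigned to the network with the higher spatial
#' weight at that vertex (ties go to network 1). The donor is that network's
#' unique vertex closest in vectorized (flat grayordinate) index, ties broken
#' toward the lower index, with replacement. Donor series are averaged across
#' all overlap vertices and standardized.
#'
#' @param data `V x T` vertex timeseries for the run.
#' @param maps `K x V` weight maps (or `mode_set`) used for the donor rule.
#' @param assignment A [assign_vertices()] result.
#' @return Standardized length-`T` series.
#' @export
mix_interdig <- function(data, maps, assignment) {
  maps <- as_maps(maps)
  sets <- donor_sets(assignment)
  wi <- maps[assignment$pair[1], ]; wj <- maps[assignment$pair[2], ]
  nearest <- function(v, pool) {
    d <- abs(pool - v)
    pool[which.min(d)]  # which.min takes the first (lowest-index) minimum
  }
  donors <- vapply(sets$overlap, function(v) {
    if (wi[v] >= wj[v]) nearest(v, sets$n1) else nearest(v, sets$n2)
  }, 1L)
  s <- colMeans(as.matrix(data)[donors, , drop = FALSE])
  if (is_zero_var(s)) degenerate("mix_interdig: zero-variance average")
  zscore(s)
}

donor_sets <- function(assignment) {
  stopifnot(inherits(assignment, "pair_assignment"))
  idx <- split(seq_along(assignment$labels), assignment$labels)
  if (length(idx$OVERLAP) == 0L) degenerate("empty overlap region")
  if (length(idx$N1) == 0L || length(idx$N2) == 0L)
    degenerate("empty unique vertex set")
  list(n1 = idx$N1, n2 = idx$N2, overlap = idx$OVERLAP)
}

degenerate <- function(msg) {
  stop(structure(class = c("netoverlap_degenerate", "error", "condition"),
                 list(message = msg, call = NULL)))
}

check_same_length <- function(n1, n2) {
  if (length(n1) != length(n2))
    stop("series lengths differ", call. = FALSE)
  if (length(n1) < 2L) stop("series too short", call. = FALSE)
  invisible(NULL)
}

#' Generate all eight semi-simulated overlap timeseries for one run
#'
#' Builds the eight mechanistic reconstructions of the overlap timeseries:
#' block switching at 50, 25 and 10 TRs, per-TR max switching, linear additive
#' and nonlinear multiplicative coupling (all from the standardized `n1`/`n2`
#' summaries), and the random-mixture and interdigitation variants (from raw
#' vertex timeseries). A variant whose construction is degenerate (e.g. a
#' zero-variance product) is stored as `NULL` and listed in `flags`.
#'
#' @param data `V x T` vertex timeseries for the run.
#' @param maps `K x V` weight maps (or `mode_set`).
#' @param assignment A [assign_vertices()] result.
#' @param summary A [extract_summary()] result for the same run (computed if
#'   omitted).
#' @param block_lens Block lengths for the three block-switching variants
#'   (default `c(50, 25, 10)` TRs).
#' @return Object of class `semisim_bundle`: named list of standardized
#'   series (`switch_50`, `switch_25`, `switch_10`, `max_switch`,
#'   `linear_add`, `nonlin_mult`, `mix_random`, `mix_interdig`), plus `flags`.
#' @export
semisim_bundle <- function(data, maps, assignment, summary = NULL,
                           block_lens = c(50L, 25L, 10L)) {
  if (is.null(summary)) summary <- extract_summary(data, assignment)
  if (!isTRUE(summary$ok))
    stop(sprintf("summary extraction flagged: %s", summary$flag), call. = FALSE)
  n1 <- summary$n1; n2 <- summary$n2
  variants <- list()
  flags <- character(0)
  add <- function(name, expr) {
    res <- tryCatch(expr, netoverlap_degenerate = function(e) {
      flags[[name]] <<- conditionMessage(e)
      NULL
    })
    variants[[name]] <<- res
  }
  add("switch_50", switch_blocks(n1, n2, block_lens[1]))
  add("switch_25", switch_blocks(n1, n2, block_lens[2]))
  add("switch_10", switch_blocks(n1, n2, block_lens[3]))
  add("max_switch", max_switch(n1, n2))
  add("linear_add", linear_add(n1, n2))
  add("nonlin_mult", nonlin_mult(n1, n2))
  add("mix_random", mix_random(data, assignment))
  add("mix_interdig", mix_interdig(data, maps, assignment))
  structure(list(variants = variants, flags = flags,
                 block_lens = block_lens, pair = assignment$pair),
            class = "semisim_bundle")
}

#' @export
print.semisim_bundle <- function(x, ...) {
  ok <- names(x$variants)[!vapply(x$variants, is.null, TRUE)]
  cat(sprintf("<semisim_bundle> pair (%d, %d); %d/8 variants: %s\n",
              x$pair[1], x$pair[2], length(ok), paste(ok, collapse = ", ")))
  if (length(x$flags)) cat("flagged:", paste(names(x$flags), collapse = ", "), "\n")
  invisible(x)
}
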