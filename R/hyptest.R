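adj_r2_of <- function(r2, n, p) 1 - (1 - r2) * (n - 1) / (n - p - 1)

#' Fit a no-intercept GLM on standardized variables
#'
#' The dependent and independent variables are demeaned and variance
#' normalized before the fit, so no intercept term is included; the absorbed
#' mean still counts as a degree of freedom in the adjustment. `R^2` is
#' `1 - SSres / sum(y^2)` and the adjusted value is
#' `1 - (1 - R^2) (n - 1) / (n - p - 1)`.
#'
#' @param y Response series.
#' @param X Regressor series: vector or `T x p` matrix.
#' @param standardize Standardize `y` and the columns of `X` first
#'   (default `TRUE`).
#' @return Object of class `overlap_glm`: `betas`, `r2`, `adj_r2`, `n_obs`,
#'   `n_regressors`.
#' @export
#' @examples
#' x <- rnorm(50); fit_glm(2 * x + rnorm(50), x)
fit_glm <- function(y, X, standardize = TRUE) {
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop("length mismatch between y and X", call. = FALSE)
  if (anyNA(y) || anyNA(X)) stop("NA values in y or X", call. = FALSE)
  if (standardize) {
    y <- zscore(y)
    X <- apply(X, 2, zscore)
  }
  n <- length(y); p <- ncol(X)
  if (n <= p + 1) stop("too few observations for the adjustment", call. = FALSE)
  qx <- qr(X)
  if (qx$rank < p) {
    kap <- kappa(X, exact = TRUE)
    stop(sprintf("collinear regressors (condition number %.3g)", kap),
         call. = FALSE)
  }
  betas <- qr.coef(qx, y)
  res <- y - X %*% betas
  r2 <- 1 - sum(res^2) / sum(y^2)
  structure(list(betas = as.numeric(betas), r2 = r2,
                 adj_r2 = adj_r2_of(r2, n, p),
                 n_obs = n, n_regressors = p),
            class = "overlap_glm")
}

#' @export
print.overlap_glm <- function(x, ...) {
  cat(sprintf("<overlap_glm> p=%d, n=%d: R2 = %.4f, adjusted R2 = %.4f\n",
              x$n_regressors, x$n_obs, x$r2, x$adj_r2))
  invisible(x)
}

#' Tidy an overlap GLM fit
#'
#' @param x An `overlap_glm`.
#' @param ... Unused.
#' @return Tibble with `term` and `estimate` per regressor.
#' @export
tidy.overlap_glm <- function(x, ...) {
  tibble::tibble(term = paste0("beta", seq_len(x$n_regressors)),
                 estimate = x$betas)
}

#' Glance at an overlap GLM fit
#'
#' @param x An `overlap_glm`.
#' @param ... Unused.
#' @return One-row tibble: `r.squared`, `adj.r.squared`, `nobs`, `df`.
#' @export
glance.overlap_glm <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, adj.r.squared = x$adj_r2,
                 nobs = x$n_obs, df = x$n_regressors)
}

roll_sum <- function(x, w, starts) {
  cs <- cumsum(x)
  cs[starts + w - 1L] - c(0, cs)[starts]
}

#' Sliding-window switching GLM
#'
#' Tests the temporal-switching hypothesis: within each sliding window of
#' `window` timepoints (step `step`) two single-regressor models are fit,
#' `O_w = b1 N1_w` and `O_w = b2 N2_w`, on the globally standardized series
#' (no per-window re-standardization); the better model's adjusted `R^2` is
#' recorded and averaged across windows. A window where the response or both
#' regressors have zero variance is skipped and counted.
#'
#' @param o,n1,n2 Length-`T` standardized summary timeseries.
#' @param window Window length in TRs (default 10).
#' @param step Window step in TRs (default 1).
#' @return List: `mean_adj_r2`, `n_windows` (used), `n_skipped`,
#'   `per_window` adjusted `R^2` values, `window`, `step`.
#' @export
glm_switching <- function(o, n1, n2, window = 10L, step = 1L) {
  check_same_length(o, n1); check_same_length(o, n2)
  T <- length(o)
  if (T < window) stop("series shorter than the window", call. = FALSE)
  zo <- zscore(o); z1 <- zscore(n1); z2 <- zscore(n2)
  starts <- seq.int(1L, T - window + 1L, by = step)
  w <- window
  syy <- roll_sum(zo^2, w, starts);  sy <- roll_sum(zo, w, starts)
  r2_one <- function(zx) {
    sxx <- roll_sum(zx^2, w, starts)
    sxy <- roll_sum(zo * zx, w, starts)
    sx <- roll_sum(zx, w, starts)
    vx <- sxx / w - (sx / w)^2
    r2 <- ifelse(sxx > 0, sxy^2 / (sxx * syy), NA_real_)
    r2[vx < 1e-12] <- NA_real_
    r2
  }
  vy <- syy / w - (sy / w)^2
  r2 <- pmax(r2_one(z1), r2_one(z2), na.rm = TRUE)
  r2[vy < 1e-12] <- NA_real_
  skipped <- !is.finite(r2)
  vals <- adj_r2_of(r2[!skipped], w, 1L)
  list(mean_adj_r2 = mean(vals), n_windows = sum(!skipped),
       n_skipped = sum(skipped), per_window = vals,
       window = as.integer(window), step = as.integer(step))
}

#' Coupling GLMs (linear, combined, interaction-only)
#'
#' Fits the three coupling models on standardized series: linear
#' `O = b1 N1 + b2 N2`; combined `O = b1 N1 + b2 N2 + b3 I`; interaction-only
#' `O = b3 I`, where the interaction `I` is the pointwise product of `N1` and
#' `N2` after clamping each to a minimum of zero, standardized before fitting.
#' A zero-variance interaction flags the combined and interaction-only fits.
#'
#' @param o,n1,n2 Length-`T` summary timeseries.
#' @return List of `overlap_glm`s: `linear`, `combined`, `nonlinear` (the
#'   latter two `NULL` when flagged), plus `flags`.
#' @export
glm_coupling <- function(o, n1, n2) {
  check_same_length(o, n1); check_same_length(o, n2)
  zo <- zscore(o); z1 <- zscore(n1); z2 <- zscore(n2)
  inter_raw <- pmax(z1, 0) * pmax(z2, 0)
  flags <- character(0)
  linear <- fit_glm(zo, cbind(n1 = z1, n2 = z2), standardize = FALSE)
  if (is_zero_var(inter_raw)) {
    flags <- c(flags, "zero-variance interaction regressor")
    combined <- NULL; nonlinear <- NULL
  } else {
    inter <- zscore(inter_raw)
    combined <- fit_glm(zo, cbind(n1 = z1, n2 = z2, interaction = inter),
                        standardize = FALSE)
    nonlinear <- fit_glm(zo, cbind(interaction = inter), standardize = FALSE)
  }
  list(linear = linear, combined = combined, nonlinear = nonlinear,
       flags = flags)
}

#' Per-vertex spatial-mixture GLM
#'
#' Tests the spatial mixing hypothesis: a separate two-regressor GLM
#' `O_v = b1v N1 + b2v N2` is fit to each vertex timeseries in the overlap
#' region, and the adjusted `R^2` is averaged across vertices. Zero-variance
#' vertex series are skipped and counted.
#'
#' @param vertex_o_data `V_O x T` matrix of overlap-region vertex timeseries.
#' @param n1,n2 Length-`T` summary timeseries.
#' @return List: `mean_adj_r2`, `per_vertex`, `n_vertices` (used),
#'   `n_skipped`.
#' @export
glm_mixture <- function(vertex_o_data, n1, n2) {
  Y <- as.matrix(vertex_o_data)
  if (nrow(Y) < 1L) stop("no overlap vertices", call. = FALSE)
  if (ncol(Y) != length(n1)) stop("length mismatch", call. = FALSE)
  X <- cbind(zscore(n1), zscore(n2))
  m <- rowMeans(Y)
  sd_v <- sqrt(rowMeans((Y - m)^2))
  keep <- sd_v >= 1e-12
  Z <- (Y[keep, , drop = FALSE] - m[keep]) / sd_v[keep]
  T <- ncol(Y)
  XtX <- crossprod(X)
  B <- solve(XtX, t(X) %*% t(Z))                  # 2 x V_kept
  fit_ss <- colSums(B * (XtX %*% B))              # b' X'X b per vertex
  cross <- colSums((t(X) %*% t(Z)) * B)           # b' X'y per vertex
  ss_res <- T - 2 * cross + fit_ss                # each z row has sum(y^2) = T
  r2 <- 1 - ss_res / T
  vals <- adj_r2_of(r2, T, 2L)
  list(mean_adj_r2 = mean(vals), per_vertex = vals,
       n_vertices = sum(keep), n_skipped = sum(!keep))
}

#' One-sided power spectrum normalized to a maximum of 1
#'
#' Discrete Fourier transform of the series on the one-sided frequency grid
#' `0 .. floor(T/2) / (T * tr)` Hz (upper limit the Nyquist frequency
#' `1 / (2 tr)` for even `T`), with power normalized so the maximum is 1.
#'
#' @param series Length-`T` numeric series (`T >= 8`), non-constant.
#' @param tr Repetition time in seconds.
#' @return Tibble with `frequency` (Hz) and `power` (max 1).
#' @export
power_spectrum <- function(series, tr) {
  stopifnot_scalar(tr, "tr")
  T <- length(series)
  if (T < 8L) stop("need at least 8 timepoints", call. = FALSE)
  if (is_zero_var(series))
    stop("constant series: normalized spectrum undefined", call. = FALSE)
  nf <- floor(T / 2) + 1L
  pw <- Mod(stats::fft(series))[seq_len(nf)]^2
  tibble::tibble(frequency = (seq_len(nf) - 1) / (T * tr),
                 power = pw / max(pw))
}

#' Correlate the original overlap series with each semi-simulated variant
#'
#' @param o Standardized original overlap timeseries for the run.
#' @param bundle A [semisim_bundle()] for the same run (flagged variants are
#'   omitted).
#' @return Tibble with one row per available variant: `variant`, `r`, `z`
#'   (Fisher-z of `r`).
#' @export
compare_correlations <- function(o, bundle) {
  stopifnot(inherits(bundle, "semisim_bundle"))
  ok <- bundle$variants[!vapply(bundle$variants, is.null, TRUE)]
  r <- vapply(ok, function(v) stats::cor(o, v), 1.0)
  tibble::tibble(variant = names(ok), r = unname(r), z = fisher_z(unname(r)))
}

median_ranking <- function(df, key, value) {
  df |>
    dplyr::group_by(.data[[key]]) |>
    dplyr::summarise(median = stats::median(.data[[value]]),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$median)) |>
    dplyr::mutate(rank = dplyr::row_number())
}

# paired two-sided t-tests between adjacent ranks; observations are matched
# on every column other than `key` and the value columns
adjacent_paired_tests <- function(df, ranking, key, value) {
  keys <- setdiff(names(df), c(key, "r", "z", "adj_r2", "r2"))
  out <- vector("list", max(0L, nrow(ranking) - 1L))
  for (k in seq_along(out)) {
    top <- ranking[[key]][k]; nxt <- ranking[[key]][k + 1L]
    wide <- df |>
      dplyr::filter(.data[[key]] %in% c(top, nxt)) |>
      dplyr::select(dplyr::all_of(c(keys, key, value))) |>
      tidyr::pivot_wider(names_from = dplyr::all_of(key),
                         values_from = dplyr::all_of(value))
    tt <- tryCatch(stats::t.test(wide[[top]], wide[[nxt]], paired = TRUE),
                   error = function(e) NULL)  # e.g. a single paired observation
    out[[k]] <- tibble::tibble(
      higher = top, lower = nxt,
      statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
      p.value = if (is.null(tt)) NA_real_ else tt$p.value,
      df = if (is.null(tt)) NA_real_ else unname(tt$parameter))
  }
  dplyr::bind_rows(out)
}

#' Rank mechanistic hypotheses from cohort-level results
#'
#' Aggregates the per-(pair, subject, run) observations: medians per
#' semi-simulated variant (on `r`) and per GLM model (on adjusted `R^2`),
#' orderings, and paired two-sided t-tests between adjacent ranks —
#' on Fisher-z values for correlations and on raw adjusted `R^2` for GLMs.
#' The pairing unit is the (pair, subject, run) observation. The correlation
#' and GLM verdicts are reported side by side, not forced into one.
#'
#' @param corr_df Tidy tibble of correlations with columns `variant`, `r`,
#'   `z`, plus identifying columns (e.g. `subject`, `run`, `pair`).
#' @param glm_df Tidy tibble of GLM results with columns `model`, `adj_r2`,
#'   plus identifying columns.
#' @return Object of class `hypothesis_ranking`: per-branch median tables
#'   (`correlation`, `glm`), adjacent-rank paired tests, and the winners
#'   (`corr_winner`, `glm_winner` — the argmax of the medians).
#' @export
rank_hypotheses <- function(corr_df, glm_df) {
  corr_df <- tibble::as_tibble(corr_df)
  glm_df <- tibble::as_tibble(glm_df)
  corr_rank <- median_ranking(corr_df, "variant", "r")
  glm_rank <- median_ranking(glm_df, "model", "adj_r2")
  structure(list(
    correlation = list(medians = corr_rank,
                       tests = adjacent_paired_tests(corr_df, corr_rank,
                                                     "variant", "z")),
    glm = list(medians = glm_rank,
               tests = adjacent_paired_tests(glm_df, glm_rank,
                                             "model", "adj_r2")),
    corr_winner = corr_rank$variant[1],
    glm_winner = glm_rank$model[1]
  ), class = "hypothesis_ranking")
}

#' @export
print.hypothesis_ranking <- function(x, ...) {
  cat("<hypothesis_ranking>\n")
  cat(sprintf("  correlation winner: %s (median r = %.3f)\n",
              x$corr_winner, x$correlation$medians$median[1]))
  cat(sprintf("  GLM winner:         %s (median adj R2 = %.3f)\n",
              x$glm_winner, x$glm$medians$median[1]))
  invisible(x)
}
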