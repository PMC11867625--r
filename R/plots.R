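#' Plot the distribution of original-vs-semi-simulated correlations
#'
#' One box per semi-simulated variant, ordered by median correlation, pooling
#' all (pair, subject, run) observations — the standard visual summary of
#' which mechanistic reconstruction tracks the original overlap timeseries
#' best.
#'
#' @param corr_df Tidy correlation tibble (e.g. `analyze_cohort()$corr`).
#' @return A ggplot object.
#' @export
plot_correlation_distributions <- function(corr_df) {
  corr_df <- tibble::as_tibble(corr_df)
  ord <- median_ranking(corr_df, "variant", "r")$variant
  corr_df |>
    dplyr::mutate(variant = factor(.data$variant, levels = rev(ord))) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$variant, y = .data$r,
                                 fill = .data$variant)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, show.legend = FALSE) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "correlation with original overlap timeseries") +
    ggplot2::theme_minimal()
}

#' Plot the distribution of adjusted R-squared per GLM model
#'
#' @param glm_df Tidy GLM tibble (e.g. `analyze_cohort()$glm`).
#' @return A ggplot object.
#' @export
plot_glm_fits <- function(glm_df) {
  glm_df <- tibble::as_tibble(glm_df)
  ord <- median_ranking(glm_df, "model", "adj_r2")$model
  glm_df |>
    dplyr::mutate(model = factor(.data$model, levels = rev(ord))) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$model, y = .data$adj_r2,
                                 fill = .data$model)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, show.legend = FALSE) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "adjusted R²") +
    ggplot2::theme_minimal()
}

#' Plot normalized power spectra of original and semi-simulated series
#'
#' @param o Original overlap timeseries.
#' @param bundle A [semisim_bundle()].
#' @param tr Repetition time in seconds.
#' @return A ggplot object.
#' @export
plot_spectra <- function(o, bundle, tr) {
  stopifnot(inherits(bundle, "semisim_bundle"))
  series <- c(list(original = o),
              bundle$variants[!vapply(bundle$variants, is.null, TRUE)])
  df <- purrr::imap_dfr(series, function(x, nm)
    dplyr::mutate(power_spectrum(x, tr), series = nm))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency, y = .data$power,
                                   colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "frequency (Hz)", y = "normalized power") +
    ggplot2::theme_minimal()
}

#' Heatmap of a spatial overlap matrix
#'
#' @param object An [overlap_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.overlap_matrix <- function(object, ...) {
  K <- nrow(object$values)
  df <- tidyr::expand_grid(mode_i = seq_len(K), mode_j = seq_len(K)) |>
    dplyr::mutate(r = as.vector(t(object$values)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mode_j, y = .data$mode_i,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::scale_y_reverse(breaks = seq_len(K)) +
    ggplot2::scale_x_continuous(breaks = seq_len(K)) +
    ggplot2::labs(x = "mode", y = "mode", fill = "r") +
    ggplot2::theme_minimal()
}

#' Bar chart of area covered at each overlap count level
#'
#' @param object An [overlap_count_map()].
#' @param ... Unused.
#' @return A ggplot object showing total area at count levels 2, 3, 4, 5+.
#' @export
autoplot.overlap_count_map <- function(object, ...) {
  df <- dplyr::filter(object$level_areas, .data$level %in% c("2", "3", "4", "5+"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level, y = .data$area_mm2)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "overlapping networks", y = "area (mm²)") +
    ggplot2::theme_minimal()
}
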