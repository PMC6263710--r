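#' Plot an AU stream
#'
#' Faceted per-AU intensity traces; frames gated out of the valid mask are
#' drawn in grey.
#'
#' @param object An [as_au_stream()] tibble.
#' @param aus AU columns to show (default all 14).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot au_stream
#' @export
autoplot.au_stream <- function(object, aus = au_columns(), ...) {
  long <- tibble::as_tibble(object) |>
    dplyr::select("time_s", "valid", dplyr::all_of(aus)) |>
    tidyr::pivot_longer(dplyr::all_of(aus), names_to = "au", values_to = "intensity")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$intensity,
                                     colour = .data$valid, group = 1)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black", `FALSE` = "grey70"),
                                 guide = "none") +
    ggplot2::facet_wrap(~au, ncol = 2) +
    ggplot2::labs(x = "time (s)", y = "AU intensity (0-5)") +
    ggplot2::theme_minimal()
}

#' Plot a variation series
#'
#' Per-AU variation scores V over time; masked (undefined) stretches appear
#' as gaps.
#'
#' @param object A [variation_series()] tibble.
#' @param aus AU columns to show (default all 14).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot variation_series
#' @export
autoplot.variation_series <- function(object, aus = au_columns(), ...) {
  dat <- dplyr::filter(tibble::as_tibble(object), .data$au %in% aus)
  ggplot2::ggplot(dat, ggplot2::aes(.data$time_s, .data$v)) +
    ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::facet_wrap(~au, ncol = 2, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "variation score V") +
    ggplot2::theme_minimal()
}

#' Plot session production scores
#'
#' Per-expression mean production scores for the upper and lower face, the
#' session-summary view used to compare expressions and face parts.
#'
#' @param object A [score_session()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot session_scores
#' @export
autoplot.session_scores <- function(object, ...) {
  sm <- session_summary(object) |>
    tidyr::pivot_longer(c("mean_m_uf", "mean_m_lf"),
                        names_to = "part", values_to = "mean_score") |>
    dplyr::mutate(part = ifelse(.data$part == "mean_m_uf", "upper face", "lower face"))
  ggplot2::ggplot(sm, ggplot2::aes(.data$expression, .data$mean_score,
                                   fill = .data$part)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = c(attr(object, "low_bound"),
                                       attr(object, "high_bound")),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "expression", y = "mean production score", fill = NULL) +
    ggplot2::theme_minimal()
}
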