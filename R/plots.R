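# ggplot2 visualisations of the cohort results.

#' Plot mean leg volume against BMI
#'
#' Scatter of the per-subject mean leg volume (averaged over scans) against
#' BMI, coloured by workflow variant, one facet per side.
#'
#' @param pairs Paired-measurement tibble from [pair_measurements()].
#' @param subjects Subject tibble with `subject_id` and `bmi`.
#' @return A ggplot object.
#' @export
plot_volume_by_bmi <- function(pairs, subjects) {
  df <- dplyr::inner_join(pairs, dplyr::select(subjects, "subject_id", "bmi"),
                          by = "subject_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bmi, y = .data$mean_volume,
                                   colour = .data$variant)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$side)) +
    ggplot2::labs(x = "BMI (kg/m²)", y = "Mean leg volume (mL)",
                  colour = "Workflow") +
    ggplot2::theme_minimal()
}

#' Plot relative scan-rescan difference by workflow variant
#'
#' Boxplots of the relative percent difference between repeated scans,
#' grouped by workflow variant, one facet per side.
#'
#' @param pairs Paired-measurement tibble from [pair_measurements()].
#' @return A ggplot object.
#' @export
plot_rel_diff_by_variant <- function(pairs) {
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$variant, y = .data$rel_diff_pct,
                                      fill = .data$variant)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5, show.legend = FALSE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$side)) +
    ggplot2::labs(x = "Workflow variant",
                  y = "Relative scan-rescan difference (%)") +
    ggplot2::theme_minimal()
}
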