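# ggplot2 views of the main result types.

#' @describeIn select_subtypes Scatter of arrays in the standardized
#'   IAE-BPS plane, colored by subtype.
#' @param object A `nurepress_subtypes` object.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.nurepress_subtypes <- function(object, ...) {
  ggplot2::ggplot(object$assignments,
                  ggplot2::aes(x = .data$iae_z, y = .data$bps_z,
                               colour = .data$subtype)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = "internal accessibility enrichment (z)",
      y = "boundary polarity strength (z)",
      colour = "subtype",
      title = sprintf("Accessibility subtypes (k = %d, silhouette = %.2f)",
                      object$k, object$silhouette)
    ) +
    ggplot2::theme_minimal()
}

#' Aggregate accessibility profile per subtype
#'
#' Mean binned insertion signal over the array body for each subtype:
#' boundary-transition arrays show a closed interior, accessibility-
#' uniform arrays a flat profile.
#'
#' @param profiles Tibble from [profile_arrays()].
#' @param subtypes A `nurepress_subtypes` object (or a tibble with
#'   `array_id`, `subtype`).
#' @return A ggplot object.
#' @export
plot_subtype_profiles <- function(profiles, subtypes) {
  lab <- if (inherits(subtypes, "nurepress_subtypes")) {
    subtypes$assignments[, c("array_id", "subtype")]
  } else {
    subtypes[, c("array_id", "subtype")]
  }
  df <- profiles |>
    left_join(lab, by = "array_id") |>
    mutate(bin = map(.data$bins, ~ tibble(bin = seq_along(.x), signal = .x))) |>
    select("array_id", "subtype", "bin") |>
    tidyr::unnest("bin") |>
    group_by(.data$subtype, .data$bin) |>
    summarise(signal = mean(.data$signal), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$signal,
                                   colour = .data$subtype)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "array body bin", y = "mean insertion signal (CPM)",
                  colour = "subtype") +
    ggplot2::theme_minimal()
}

#' Ranked repressor predictions per subtype
#'
#' Horizontal bars of the top TFs by repressor prediction score within
#' each subtype, filled by specificity score (values near zero indicate
#' subtype-shared enrichment).
#'
#' @param scores Score tibble from [score_and_rank()].
#' @param top_n Number of TFs per subtype.
#' @return A ggplot object.
#' @export
plot_repressor_scores <- function(scores, top_n = 20L) {
  df <- scores |>
    group_by(.data$sample_id, .data$subtype) |>
    arrange(desc(.data$rps), .by_group = TRUE) |>
    dplyr::slice_head(n = top_n) |>
    ungroup()
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$rps, y = stats::reorder(.data$tf, .data$rps),
    fill = .data$s_score
  )) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~ .data$subtype, scales = "free") +
    ggplot2::scale_fill_gradient2(low = "#4575b4", mid = "grey85",
                                  high = "#d73027", midpoint = 0) +
    ggplot2::labs(x = "repressor prediction score (RE x MP)", y = NULL,
                  fill = "specificity") +
    ggplot2::theme_minimal()
}
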