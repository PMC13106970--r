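#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# min-max to [0,1]; all-equal inputs map to the neutral 0.5.
minmax <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) return(rep(0.5, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Composite accuracy score per transform
#'
#' Within each dataset, per-sample Pearson values (over all samples and
#' transforms jointly) are min-max scaled to \[0,1\]; RMSE values are first
#' inverted (dataset maximum minus value) and then scaled likewise. The
#' normalized values are averaged per transform within the dataset, then
#' across datasets, and the final accuracy is the arithmetic mean of the two
#' metric summaries. Degenerate min-max (all values equal) maps to 0.5.
#'
#' @param metrics Tibble with columns `dataset`, `transform`, `pearson`,
#'   `rmse` (one row per evaluated sample).
#' @return Tibble: `transform`, `accuracy`, `pearson_score`, `rmse_score`.
#' @export
accuracy_score <- function(metrics) {
  needed <- c("dataset", "transform", "pearson", "rmse")
  if (!all(needed %in% names(metrics)) || !nrow(metrics)) {
    rlang::abort("metrics must be a nonempty tibble with dataset/transform/pearson/rmse")
  }
  per_dataset <- metrics |>
    dplyr::group_by(.data$dataset) |>
    dplyr::mutate(p_norm = minmax(.data$pearson),
                  r_norm = minmax(max(.data$rmse) - .data$rmse)) |>
    dplyr::group_by(.data$dataset, .data$transform) |>
    dplyr::summarise(p_norm = mean(.data$p_norm), r_norm = mean(.data$r_norm),
                     .groups = "drop")
  per_dataset |>
    dplyr::group_by(.data$transform) |>
    dplyr::summarise(pearson_score = mean(.data$p_norm),
                     rmse_score = mean(.data$r_norm), .groups = "drop") |>
    dplyr::mutate(accuracy = (.data$pearson_score + .data$rmse_score) / 2) |>
    dplyr::relocate("transform", "accuracy")
}

#' Composite robustness score per transform
#'
#' Pools each axis's cosine similarities (donor pairs within transform;
#' transform pairs excluding self-comparisons), min-max scales each pooled
#' axis to \[0,1\], averages per transform per axis, and takes the mean of
#' the two axis scores.
#'
#' @param donor_pairs Tibble: `transform`, `cosine` — one row per donor pair
#'   per transform.
#' @param transform_pairs Tibble: `transform`, `cosine` — off-diagonal
#'   entries of the inter-transform concordance (see [concordance_long()]).
#' @return Tibble: `transform`, `robustness`, `donor_score`,
#'   `transform_score`.
#' @export
robustness_score <- function(donor_pairs, transform_pairs) {
  if (!nrow(donor_pairs) || !nrow(transform_pairs)) {
    rlang::abort("both robustness axes need at least one pair")
  }
  donor <- donor_pairs |>
    dplyr::mutate(norm = minmax(.data$cosine)) |>
    dplyr::group_by(.data$transform) |>
    dplyr::summarise(donor_score = mean(.data$norm), .groups = "drop")
  trans <- transform_pairs |>
    dplyr::mutate(norm = minmax(.data$cosine)) |>
    dplyr::group_by(.data$transform) |>
    dplyr::summarise(transform_score = mean(.data$norm), .groups = "drop")
  dplyr::full_join(donor, trans, by = "transform") |>
    dplyr::mutate(robustness = (.data$donor_score + .data$transform_score) / 2) |>
    dplyr::relocate("transform", "robustness")
}

#' Combine accuracy and robustness into a composite score table
#'
#' @param accuracy [accuracy_score()] output.
#' @param robustness [robustness_score()] output.
#' @return A `composite_scores` tibble: `transform`, `accuracy`,
#'   `robustness`, plus the per-axis intermediates.
#' @export
composite_scores <- function(accuracy, robustness) {
  out <- dplyr::full_join(accuracy, robustness, by = "transform")
  structure(out, class = c("composite_scores", class(out)))
}

#' Accuracy-robustness landscape plot
#'
#' One point per transform; transforms in the upper-right corner are both
#' accurate on pseudobulk ground truth and consistent across donors and
#' transforms.
#'
#' @param object A [composite_scores()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot composite_scores
#' @export
autoplot.composite_scores <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$robustness, y = .data$accuracy,
                               label = .data$transform)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::labs(x = "Robustness score", y = "Accuracy score") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Point-range plot of per-transform metric summaries
#'
#' @param summaries Tibble with `transform`, a mean column and low/high CI
#'   columns (see [glance.scenario_metrics()]).
#' @param metric `"pearson"` or `"rmse"`.
#' @return A ggplot object.
#' @export
plot_metric_summary <- function(summaries, metric = c("pearson", "rmse")) {
  metric <- match.arg(metric)
  cols <- paste0(metric, c("_mean", "_low", "_high"))
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = stats::reorder(.data$transform,
                                                  .data[[cols[1]]]),
                               y = .data[[cols[1]]])) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data[[cols[2]]],
                                          ymax = .data[[cols[3]]])) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = paste(metric, "(mean, 95% bootstrap CI)")) +
    ggplot2::theme_minimal()
}

#' Heatmap of a concordance matrix
#'
#' @param cm A [concordance_matrix()].
#' @return A ggplot object.
#' @export
plot_concordance <- function(cm) {
  df <- as.data.frame(as.table(unclass(cm)))
  names(df) <- c("a", "b", "cosine")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b,
                                   fill = .data$cosine)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(min(df$cosine), 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "cosine") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
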