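#' Recovery scatter of true versus fitted parameters
#'
#' One panel per parameter, with the identity line and the Pearson
#' correlation annotated; the standard visual check of a parameter-recovery
#' harness.
#'
#' @param truth,fitted Data frames with `subject_id` and shared numeric
#'   parameter columns (e.g. the flattened columns of
#'   [generate_perception_truth()] and [fit_perception()]).
#' @param params Character vector of parameter columns to show; defaults to
#'   all shared numeric columns.
#' @return A ggplot object.
#' @export
plot_recovery <- function(truth, fitted, params = NULL) {
  shared <- intersect(names(truth), names(fitted))
  shared <- setdiff(shared[vapply(truth[shared], is.numeric, logical(1))],
                    "subject_id")
  if (!is.null(params)) shared <- intersect(shared, params)
  long <- dplyr::inner_join(
    tidyr::pivot_longer(truth[c("subject_id", shared)], -"subject_id",
                        names_to = "parameter", values_to = "truth"),
    tidyr::pivot_longer(fitted[c("subject_id", shared)], -"subject_id",
                        names_to = "parameter", values_to = "fitted"),
    by = c("subject_id", "parameter")
  )
  labels <- long |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(r = cor(.data$truth, .data$fitted), .groups = "drop") |>
    dplyr::mutate(label = sprintf("r = %.2f", .data$r))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$truth, y = .data$fitted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_text(data = labels, ggplot2::aes(label = .data$label),
                       x = -Inf, y = Inf, hjust = -0.2, vjust = 1.5,
                       inherit.aes = FALSE, size = 3) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "generating value", y = "recovered value") +
    ggplot2::theme_minimal()
}

#' Cohort distributions of fitted perception parameters
#'
#' Violin-and-point summaries of the task-relevant sensitivities and
#' evidence biases across subjects.
#'
#' @param perception_fits A [fit_perception()] tibble.
#' @return A ggplot object.
#' @export
plot_perception_cohort <- function(perception_fits) {
  long <- perception_fits |>
    dplyr::select("subject_id", dplyr::starts_with("S_"),
                  dplyr::starts_with("Bias_")) |>
    tidyr::pivot_longer(-"subject_id", names_to = "parameter") |>
    tidyr::separate_wider_delim("parameter", "_", names = c("kind", "condition"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition, y = .data$value)) +
    ggplot2::geom_violin(fill = "grey90") +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6, size = 1) +
    ggplot2::facet_wrap(~kind, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "estimate") +
    ggplot2::theme_minimal()
}

#' Scatter of a cross-task association
#'
#' One linking correlation (e.g. merit sensitivity against merit-related
#' change in other-regard) with a rank-based trend annotation.
#'
#' @param linked A [build_linked_dataset()] tibble.
#' @param x,y Column names to plot.
#' @return A ggplot object.
#' @export
plot_linking <- function(linked, x, y) {
  df <- linked[linked$complete, c(x, y)]
  names(df) <- c("x", "y")
  rho <- suppressWarnings(cor.test(df$x, df$y, method = "spearman"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::labs(x = x, y = y,
                  subtitle = sprintf("Spearman rho = %.2f, p = %.3g",
                                     rho$estimate, rho$p.value)) +
    ggplot2::theme_minimal()
}
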