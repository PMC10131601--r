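#' Love plot of covariate balance
#'
#' Dot plot of standardized mean differences per feature with the
#' conventional +/- 0.1 balance band.
#'
#' @param object A `pupm_balance`.
#' @param threshold Balance band half-width.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pupm_balance <- function(object, threshold = 0.1, ...) {
  df <- tibble::as_tibble(object)
  df <- df[is.finite(df$smd), , drop = FALSE]
  df$feature <- stats::reorder(df$feature, abs(df$smd))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$smd, y = .data$feature)) +
    ggplot2::geom_vline(xintercept = c(-threshold, threshold),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "standardized mean difference (treated - comparison)",
                  y = NULL, title = "Covariate balance after matching") +
    ggplot2::theme_minimal()
}

#' Forest plot of effect estimates
#'
#' @param object A `pupm_effect` table (e.g. from [category_breakdown()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pupm_effect <- function(object, ...) {
  df <- tidy(object)
  df$label <- factor(df$label, levels = rev(df$label))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "savings, USD per user per month (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Pre/post mean PUPM spending by group
#'
#' Bar chart of group mean PUPM spending in the pre- and post-enlistment
#' periods, the visual companion of the difference-in-differences estimate.
#'
#' @param summaries A `pupm_spend` table.
#' @return A ggplot.
#' @export
plot_prepost <- function(summaries) {
  df <- tibble::as_tibble(summaries) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(pre = mean(.data$pre_pupm), post = mean(.data$post_pupm),
                     .groups = "drop") |>
    tidyr::pivot_longer(c("pre", "post"), names_to = "period", values_to = "pupm")
  df$period <- factor(df$period, levels = c("pre", "post"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$period, y = .data$pupm,
                                   fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "mean spending, USD per user per month",
                  fill = NULL, title = "Average PUPM spending before and after enlistment") +
    ggplot2::theme_minimal()
}

#' Plot a pipeline manifest
#'
#' @param object A `pupm_manifest`.
#' @param ... Unused.
#' @return The [plot_prepost()] chart for the run's summaries.
#' @export
autoplot.pupm_manifest <- function(object, ...) {
  plot_prepost(object$summaries)
}
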