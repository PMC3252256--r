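#' Bland-Altman plot
#'
#' Differences (pharmacy - ward) against pair averages, with the mean
#' difference (dashed) and limits of agreement (shaded band).
#'
#' @param object an [bland_altman()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.abx_bland_altman <- function(object, ...) {
  ggplot2::ggplot(
    object$data,
    ggplot2::aes(x = .data$average, y = .data$difference)
  ) +
    ggplot2::annotate(
      "rect",
      xmin = -Inf, xmax = Inf,
      ymin = object$loa_low, ymax = object$loa_high,
      alpha = 0.15
    ) +
    ggplot2::geom_hline(
      yintercept = object$mean_difference, linetype = "dashed"
    ) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      x = "Average of pharmacy and ward DDDs",
      y = "Pharmacy - ward difference (DDDs)",
      title = sprintf(
        "Bland-Altman: mean difference %.3f, limits %.2f to %.2f (n = %d)",
        object$mean_difference, object$loa_low, object$loa_high,
        object$n_pairs
      )
    )
}

#' Weekly consumption, pharmacy vs ward, all wards combined
#'
#' @param pharm,ward consumption series tibbles.
#' @return a ggplot object with one line per method.
#' @export
plot_weekly_series <- function(pharm, ward) {
  bind_rows(as_tibble(pharm), as_tibble(ward)) |>
    group_by(.data$method, .data$week) |>
    summarise(ddd = sum(.data$ddd), .groups = "drop") |>
    ggplot2::ggplot(
      ggplot2::aes(
        x = .data$week, y = .data$ddd,
        colour = .data$method, linetype = .data$method
      )
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "Study week", y = "DDDs per week", colour = NULL, linetype = NULL
    )
}

#' Order-size distribution per agent
#'
#' Boxplots of DDDs per pharmacy order by agent, the diagnostic for the
#' small-frequent-parenteral vs lumpy-oral ordering contrast.
#'
#' @param sales a sales ledger tibble.
#' @return a ggplot object.
#' @export
plot_order_sizes <- function(sales) {
  ggplot2::ggplot(
    as_tibble(sales),
    ggplot2::aes(x = .data$agent_id, y = .data$ddd)
  ) +
    ggplot2::geom_boxplot() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "DDDs per order")
}
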