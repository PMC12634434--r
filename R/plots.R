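# ggplot2 displays for the main result types.

#' Plot a bin-centered distance histogram
#'
#' @param hist Tibble from [distance_histogram()].
#' @param fill Bar fill colour.
#' @return A ggplot object.
#' @export
plot_distance_histogram <- function(hist, fill = "grey35") {
  assert_cols(hist, c("bin_center", "count"), "hist")
  w <- if (nrow(hist) > 1) min(diff(sort(unique(hist$bin_center)))) else 1
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$bin_center, y = .data$count)) +
    ggplot2::geom_col(fill = fill, width = 0.9 * w) +
    ggplot2::labs(x = "distance (µm)", y = "cells") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.z_profile <- function(object, ...) {
  ggplot2::ggplot(object$normalized,
                  ggplot2::aes(x = .data$t_min / 60, y = .data$z_norm_um,
                               group = .data$t_min)) +
    ggplot2::geom_boxplot(outlier.size = 0.3, fill = "grey85") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(
      x = "time (h)", y = "depth - median depth (µm)",
      subtitle = sprintf("Δ median %.1f µm; SD %.1f → %.1f µm",
                         object$delta_median_um, object$sd_t0_um,
                         object$sd_tend_um)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cycle_classification <- function(object, ...) {
  df <- tidy(object)
  df$cycle_class <- factor(df$cycle_class,
                           levels = c("non_cycling", "slow_cycling",
                                      "high_cycling"))
  ggplot2::ggplot(df, ggplot2::aes(x = "sample", y = .data$fraction,
                                   fill = .data$cycle_class)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_brewer(palette = "Blues", direction = -1) +
    ggplot2::labs(x = NULL, y = "fraction of cells", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.drp_summary <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$sample_id,
                               y = .data$integrated_response,
                               fill = .data$condition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~drug) +
    ggplot2::labs(x = NULL, y = "integrated normalized viability (%)",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Depth-distribution dot plot of migration percentages
#'
#' @param migration Tibble from [migration_percent()] (needs `cell_type`,
#'   `migration_pct`).
#' @param network_percent Optional horizontal reference at the network depth.
#' @return A ggplot object.
#' @export
plot_migration_depth <- function(migration, network_percent = NULL) {
  assert_cols(migration, c("cell_type", "migration_pct"), "migration")
  p <- ggplot2::ggplot(migration,
                       ggplot2::aes(x = .data$cell_type,
                                    y = .data$migration_pct)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.6) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = "migration depth (% of gel depth)") +
    ggplot2::theme_minimal()
  if (!is.null(network_percent)) {
    p <- p + ggplot2::geom_hline(yintercept = network_percent,
                                 linetype = "dashed", colour = "red3")
  }
  p
}
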