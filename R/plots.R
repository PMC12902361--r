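# ggplot2 visualizations

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Horizon-style track of z-standardized ILS along the windows
#'
#' @param object A `genealogy_scan`.
#' @param ... Unused.
#' @return A ggplot: per-window z-standardized ILS posterior, red for
#'   ILS-poor and blue for ILS-rich regions.
#' @method autoplot genealogy_scan
#' @export
autoplot.genealogy_scan <- function(object, ...) {
  w <- object$windows
  ggplot2::ggplot(w, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                  y = .data$z_ils, fill = .data$z_ils)) +
    ggplot2::geom_col(width = w$end[1] - w$start[1]) +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "grey95",
                                  high = "steelblue4", midpoint = 0) +
    ggplot2::labs(x = "position (bp)", y = "z-standardized ILS",
                  fill = "z(ILS)") +
    ggplot2::theme_minimal()
}

#' Factor contributions of a discordance decomposition
#'
#' @param object A `discord_decomposition`.
#' @param ... Unused.
#' @return A ggplot bar chart of percent contributions.
#' @method autoplot discord_decomposition
#' @export
autoplot.discord_decomposition <- function(object, ...) {
  d <- tidy(object)
  d$term <- factor(d$term, levels = c("theta", "error", "ri"),
                   labels = c("ILS (theta)", "error (100-BP)",
                              "introgression (RI)"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$term, y = .data$percent,
                                  fill = .data$term)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(
      x = NULL, y = "% of explained heterogeneity",
      subtitle = sprintf("R² = %.3f over %d nodes", object$r2,
                         object$n_nodes)
    ) +
    ggplot2::theme_minimal()
}

#' Per-branch discordance against each candidate factor
#'
#' Scatter of `100 - gCF` against theta, `100 - BP` and RI with linear
#' trends, one facet per factor.
#'
#' @param node_stats A node-stats tibble (e.g. from [run_pipeline()]).
#' @return A ggplot.
#' @export
plot_node_stats <- function(node_stats) {
  d <- tibble::as_tibble(node_stats)
  d$discordance <- 100 - d$gcf
  d$error <- 100 - d$bp
  long <- tidyr::pivot_longer(
    d[, c("branch_id", "discordance", "theta", "error", "ri")],
    cols = c("theta", "error", "ri"),
    names_to = "factor", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value,
                                     y = .data$discordance)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, color = "steelblue4") +
    ggplot2::facet_wrap(~factor, scales = "free_x") +
    ggplot2::labs(x = "factor value", y = "discordance (100 - gCF)") +
    ggplot2::theme_minimal()
}
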