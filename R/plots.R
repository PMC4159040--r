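#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a clamp design landscape
#'
#' Per-column block conservation and pass divergence across the alignment,
#' with the primer footprint and the chosen clamp window shaded and the
#' LNA-substituted columns marked.
#'
#' @param object A `clamp_design`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.clamp_design <- function(object, ...) {
  stats <- tidyr::pivot_longer(object$column_stats,
                               c("block_conservation", "pass_divergence"),
                               names_to = "metric", values_to = "value")
  w <- object$windows[1, ]
  site <- object$primer_site
  lna_cols <- if (site$orientation == "forward") {
    w$start + object$clamp$lna_positions - 1L
  } else {
    w$end - object$clamp$lna_positions + 1L
  }
  ggplot2::ggplot(stats, ggplot2::aes(x = .data$column, y = .data$value,
                                      colour = .data$metric)) +
    ggplot2::annotate("rect", xmin = site$start - 0.5, xmax = site$end + 0.5,
                      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue") +
    ggplot2::annotate("rect", xmin = w$start - 0.5, xmax = w$end + 0.5,
                      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "darkorange") +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = lna_cols, linetype = "dotted") +
    ggplot2::labs(x = "alignment column", y = "fraction of members",
                  colour = NULL,
                  title = sprintf("%s: primer footprint (blue), clamp window (orange), LNA columns (dotted)",
                                  object$clamp$name)) +
    ggplot2::theme_minimal()
}

#' Plot coverage as a function of the mismatch budget
#'
#' @param primer A `degenerate_primer`.
#' @param seqs A `seq_set`.
#' @param budgets Integer vector of mismatch budgets to evaluate.
#' @return A ggplot object.
#' @export
plot_coverage_curve <- function(primer, seqs, budgets = 0:3) {
  df <- purrr::map_dfr(budgets, ~ coverage(primer, seqs, .x))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mismatch_budget, y = .data$fraction)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "mismatch budget", y = "coverage",
                  title = sprintf("Coverage of %s (n = %d)", primer$name, nrow(seqs))) +
    ggplot2::theme_minimal()
}
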