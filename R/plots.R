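#' Plot a benchmark report
#'
#' Bar chart of mean per-definition deltas by metric, annotated with the
#' report's significance stars. Grade metrics improving show as negative
#' bars; reading ease improving shows positive.
#'
#' @param object A `medsim_benchmark`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot medsim_benchmark
#' @export
autoplot.medsim_benchmark <- function(object, ...) {
  df <- as.data.frame(object)
  df$metric <- toupper(df$metric)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$mean_delta)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_text(
      ggplot2::aes(label = .data$stars,
                   vjust = ifelse(.data$mean_delta >= 0, -0.4, 1.2))) +
    ggplot2::labs(x = NULL, y = "Mean Δ (post − pre)",
                  title = "Readability change after hypernym substitution",
                  caption = "* p<0.05  ** p<0.01  *** p<0.005") +
    ggplot2::theme_minimal()
}

#' Pre/post metric distribution plot
#'
#' Overlaid per-definition readability distributions before and after
#' simplification, one facet per metric.
#'
#' @param pre,post Corpora (`id`, `text`).
#' @param metrics Metrics to show.
#' @return A ggplot object.
#' @export
plot_readability_shift <- function(pre, post,
                                   metrics = c("fks", "fkg", "ari", "gfi")) {
  rb <- dplyr::bind_rows(
    dplyr::mutate(readability(pre), stage = "pre"),
    dplyr::mutate(readability(post), stage = "post"))
  long <- tidyr::pivot_longer(rb[, c("id", "stage", metrics)],
                              dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  long$metric <- toupper(long$metric)
  long$stage <- factor(long$stage, levels = c("pre", "post"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, fill = .data$stage)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = "Score", y = "Density", fill = NULL,
                  title = "Per-definition readability, pre vs post") +
    ggplot2::theme_minimal()
}
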