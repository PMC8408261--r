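#' Plot single-item report distributions per presented slot
#'
#' Histogram of reported times for each presented slot, with the true
#' onset marked — the raw material behind the empirical report
#' likelihood.
#'
#' @param records Trial records (single intermediate item).
#' @param grid A [slot_grid()].
#' @param binwidth Histogram bin width in seconds.
#' @return A ggplot object.
#' @export
plot_report_distributions <- function(records, grid = slot_grid(),
                                      binwidth = 0.75) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting needs the ggplot2 package")
  d <- records
  d$onset <- slot_onset(d$presented_slot, grid)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$reported_time_s)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey60") +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$onset),
                        linetype = "dashed", colour = "red") +
    ggplot2::facet_wrap(~presented_slot) +
    ggplot2::labs(x = "reported time (s)", y = "count",
                  title = "Report distributions by presented slot")
}

#' Plot rank-conditioned average report curves
#'
#' Mean reported time versus presented onset, one line per item rank,
#' with the identity line for perfect reports. The vertical separation of
#' the rank curves at a shared slot is the order-bias effect.
#'
#' @param summary A [summarize_reports()] result (or record data.frame,
#'   summarized on the fly).
#' @param grid A [slot_grid()].
#' @return A ggplot object.
#' @export
plot_mean_reports <- function(summary, grid = slot_grid()) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting needs the ggplot2 package")
  if (!"mean_report" %in% names(summary))
    summary <- summarize_reports(summary)
  summary$onset <- slot_onset(summary$presented_slot, grid)
  summary$rank <- factor(summary$item_rank)
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$onset, y = .data$mean_report,
                               colour = .data$rank)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_report - .data$se_report,
      ymax = .data$mean_report + .data$se_report)) +
    ggplot2::labs(x = "presented time (s)", y = "mean reported time (s)",
                  colour = "item rank",
                  title = "Average reports by presentation time and rank")
}
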