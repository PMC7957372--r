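#' Plot overlaid pre/post TIR distributions
#'
#' Mirrors the population TIR-distribution display: per-user TIR values for
#' both windows binned over \[0, 100\] and overlaid, a rightward shift
#' indicating population-level improvement.
#'
#' @param metrics Metric tibble with `tir` and `window` columns (e.g.
#'   `bind_rows(pre, post)`).
#' @param bin_width Bin width in TIR points.
#' @return A ggplot object.
#' @export
plot_tir_distribution <- function(metrics, bin_width = 2.5) {
  h <- tir_histogram(metrics, bin_width)
  ggplot2::ggplot(
    h,
    ggplot2::aes(x = .data$bin_left + bin_width / 2, y = .data$count,
                 fill = .data$window)
  ) +
    ggplot2::geom_col(position = "identity", alpha = 0.5) +
    ggplot2::labs(x = "Time in range 70-180 mg/dL (%)", y = "Users",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot weekly mean trajectories
#'
#' Weekly per-group mean of a glycemic metric with a +/- SEM ribbon,
#' optionally annotated with reference dates (e.g. stay-at-home orders).
#'
#' @param trajectory Output of [weekly_trajectory()].
#' @param metric_label Y-axis label.
#' @param events Optional named `Date` vector drawn as vertical lines.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(trajectory, metric_label = "Metric",
                            events = NULL) {
  has_group <- "group" %in% names(trajectory)
  aes <- if (has_group) {
    ggplot2::aes(x = .data$week_start, y = .data$mean,
                 colour = .data$group, fill = .data$group, group = .data$group)
  } else {
    ggplot2::aes(x = .data$week_start, y = .data$mean)
  }
  p <- ggplot2::ggplot(trajectory, aes) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      alpha = 0.2, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Week", y = metric_label, colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(events)) {
    p <- p + ggplot2::geom_vline(xintercept = as.Date(events),
                                 linetype = "dashed", alpha = 0.5)
  }
  p
}

#' Plot stratified pre/post TIR means
#'
#' Per-stratum pre and post mean TIR with 95% confidence-interval error bars,
#' mirroring the income/region/tenure panels.
#'
#' @param strata Output of [stratify()] (one scheme).
#' @return A ggplot object.
#' @export
plot_strata <- function(strata) {
  long <- dplyr::bind_rows(
    dplyr::transmute(strata, stratum = .data$stratum, phase = "pre",
                     mean = .data$tir_pre_mean, lo = .data$tir_pre_lo,
                     hi = .data$tir_pre_hi),
    dplyr::transmute(strata, stratum = .data$stratum, phase = "post",
                     mean = .data$tir_post_mean, lo = .data$tir_post_lo,
                     hi = .data$tir_post_hi)
  )
  long$phase <- factor(long$phase, levels = c("pre", "post"))
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$stratum, y = .data$mean, fill = .data$phase)
  ) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2
    ) +
    ggplot2::labs(x = NULL, y = "Mean TIR (%)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot method for paired comparison objects
#'
#' Overlaid pre/post TIR distributions for the paired users of a
#' [summarize_comparison()] result.
#'
#' @param object A `cgm_comparison` object.
#' @param ... Passed to [plot_tir_distribution()].
#' @return A ggplot object.
#' @method autoplot cgm_comparison
#' @export
autoplot.cgm_comparison <- function(object, ...) {
  changes <- object$changes
  long <- tidyr::pivot_longer(
    dplyr::select(changes, "user_id", "tir_pre", "tir_post"),
    cols = c("tir_pre", "tir_post"),
    names_to = "window", values_to = "tir"
  )
  long$window <- ifelse(long$window == "tir_pre", "pre", "post")
  plot_tir_distribution(long, ...)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
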