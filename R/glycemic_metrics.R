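#' Consensus metric thresholds and goals
#'
#' Band edges and goals from the international consensus on CGM metrics:
#' target range 70--180 mg/dL (endpoints inclusive), level-2 hypoglycemia
#' below 54 mg/dL (strict), level-2 hyperglycemia above 250 mg/dL (strict),
#' a TIR goal of at least 70%, and a goal of under 5% of readings above
#' 250 mg/dL. With the target band closed on both ends, the below-70 and
#' above-180 bands are strict, which makes TIR + TBR70 + TAR180 an exact
#' partition of 100%.
#'
#' @param tir_low,tir_high Target range bounds, mg/dL.
#' @param tbr_level2 Level-2 hypoglycemia threshold, mg/dL.
#' @param tar_level2 Level-2 hyperglycemia threshold, mg/dL.
#' @param tir_goal Minimum TIR (%) counted as meeting the TIR goal.
#' @param tar250_goal Maximum percent of readings above `tar_level2` counted
#'   as meeting the hyperglycemia goal (strict `<`).
#' @return A list of class `metric_thresholds`.
#' @export
metric_thresholds <- function(tir_low = 70, tir_high = 180,
                              tbr_level2 = 54, tar_level2 = 250,
                              tir_goal = 70, tar250_goal = 5) {
  stopifnot(tbr_level2 < tir_low, tir_low < tir_high, tir_high < tar_level2)
  structure(
    list(
      tir_low = tir_low, tir_high = tir_high,
      tbr_level2 = tbr_level2, tar_level2 = tar_level2,
      tir_goal = tir_goal, tar250_goal = tar250_goal
    ),
    class = "metric_thresholds"
  )
}

#' Percent of readings in a glucose band
#'
#' @param glucose Numeric vector of readings (mg/dL); must be nonempty.
#' @param low,high Band edges; `-Inf`/`Inf` allowed for one-sided bands.
#' @param low_inclusive,high_inclusive Whether each edge is included. The
#'   target band 70--180 is inclusive on both ends; above-range bands use a
#'   strict `>`, below-range bands a strict `<`.
#' @return Percent in \[0, 100\].
#' @export
pct_in_band <- function(glucose, low, high,
                        low_inclusive = TRUE, high_inclusive = TRUE) {
  if (length(glucose) == 0L) {
    stop("pct_in_band: metric undefined on empty readings", call. = FALSE)
  }
  above_low <- if (low_inclusive) glucose >= low else glucose > low
  below_high <- if (high_inclusive) glucose <= high else glucose < high
  100 * sum(above_low & below_high) / length(glucose)
}

#' Glucose management indicator (GMI)
#'
#' The GMI is an HbA1c-like percentage, a linear function of mean glucose:
#' `GMI(%) = 3.31 + 0.02392 * mean_glucose (mg/dL)`. For cohort reporting GMI
#' is conventionally printed to 2 decimals; the returned value is exact so the
#' affine identity `gmi(a) - gmi(b) = 0.02392 * (a - b)` holds, and rounding
#' is left to the caller (or `digits`).
#'
#' @param mean_glucose Mean glucose, mg/dL; must be positive.
#' @param digits Optional rounding (e.g. `2` for reporting).
#' @return GMI in percent.
#' @examples
#' compute_gmi(173.3, digits = 2) # 7.46
#' compute_gmi(170.2, digits = 2) # 7.38
#' @export
compute_gmi <- function(mean_glucose, digits = NULL) {
  if (any(!is.finite(mean_glucose)) || any(mean_glucose <= 0)) {
    stop("compute_gmi: mean glucose must be positive and finite", call. = FALSE)
  }
  gmi <- 3.31 + 0.02392 * mean_glucose
  if (!is.null(digits)) gmi <- round(gmi, digits)
  gmi
}

#' Coefficient of variation of a glucose trace
#'
#' `100 * sample SD / mean`, the standard glycemic-variability measure. Uses
#' the n-1 sample SD. Scale-invariant.
#'
#' @param glucose Numeric vector; at least 2 readings with positive mean.
#' @return CV in percent.
#' @export
compute_cv <- function(glucose) {
  if (length(glucose) < 2L) {
    stop("compute_cv: needs at least 2 readings", call. = FALSE)
  }
  m <- mean(glucose)
  if (m <= 0) stop("compute_cv: mean must be positive", call. = FALSE)
  100 * sd(glucose) / m
}

#' Per-user consensus metrics over an observation window
#'
#' Restricts the streams to the window and computes, per user: reading count,
#' time in range (TIR, % in \[70, 180\] mg/dL), level-2 and level-1 time below
#' range (`tbr54`, `tbr70`), time above range (`tar180`, `tar250`), mean and
#' SD glucose, CV, GMI, and the two goal flags (`tir >= 70`% and
#' `tar250 < 5`%). Metrics are reading-weighted: each sensor value counts
#' equally, which at a near-uniform 5-minute cadence coincides with
#' time-weighting.
#'
#' Users with no readings inside the window are skipped (reported via
#' [message()]); under the study's inclusion filters such users have already
#' been excluded.
#'
#' @param streams Long stream tibble (`user_id`, `timestamp`, `glucose`).
#' @param window An [observation_window()].
#' @param thresholds A [metric_thresholds()] object.
#' @return Tibble, one row per user with readings in the window: `user_id`,
#'   `window`, `n_readings`, `tir`, `tbr54`, `tbr70`, `tar180`, `tar250`,
#'   `mean_glucose`, `sd_glucose`, `cv`, `gmi`, `meets_tir_goal`,
#'   `meets_tar250_goal`.
#' @export
compute_window_metrics <- function(streams, window,
                                   thresholds = metric_thresholds()) {
  stopifnot(inherits(thresholds, "metric_thresholds"))
  clipped <- window_clip(streams, window)
  n_all <- dplyr::n_distinct(streams$user_id)
  n_in <- dplyr::n_distinct(clipped$user_id)
  if (n_in < n_all) {
    message(sprintf(
      "compute_window_metrics: %d user(s) had no readings in window '%s' and were skipped",
      n_all - n_in, window$label
    ))
  }
  th <- thresholds
  out <- clipped |>
    dplyr::group_by(.data$user_id) |>
    dplyr::summarise(
      n_readings = dplyr::n(),
      tir = 100 * sum(.data$glucose >= th$tir_low & .data$glucose <= th$tir_high) / dplyr::n(),
      tbr54 = 100 * sum(.data$glucose < th$tbr_level2) / dplyr::n(),
      tbr70 = 100 * sum(.data$glucose < th$tir_low) / dplyr::n(),
      tar180 = 100 * sum(.data$glucose > th$tir_high) / dplyr::n(),
      tar250 = 100 * sum(.data$glucose > th$tar_level2) / dplyr::n(),
      mean_glucose = mean(.data$glucose),
      sd_glucose = if (dplyr::n() >= 2L) sd(.data$glucose) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      cv = 100 * .data$sd_glucose / .data$mean_glucose,
      gmi = compute_gmi(.data$mean_glucose),
      meets_tir_goal = .data$tir >= th$tir_goal,
      meets_tar250_goal = .data$tar250 < th$tar250_goal,
      window = window$label
    ) |>
    dplyr::relocate("window", .after = "user_id")
  out
}
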