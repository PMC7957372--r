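#' Classify a TIR change as clinically meaningful
#'
#' A change in time in range of at least 5 percentage points in either
#' direction is conventionally regarded as clinically meaningful. Thresholds
#' are inclusive: `+5.0` is a meaningful increase, `-5.0` a meaningful
#' decrease, anything strictly inside is `intermediate`.
#'
#' @param delta_tir Numeric vector of TIR changes (post minus pre, points).
#' @param threshold Meaningful-change magnitude, default 5.
#' @return Factor with levels `meaningful_decrease`, `intermediate`,
#'   `meaningful_increase`.
#' @export
classify_change <- function(delta_tir, threshold = 5) {
  stopifnot(threshold > 0)
  out <- dplyr::case_when(
    delta_tir >= threshold ~ "meaningful_increase",
    delta_tir <= -threshold ~ "meaningful_decrease",
    TRUE ~ "intermediate"
  )
  factor(out, levels = c("meaningful_decrease", "intermediate",
                         "meaningful_increase"))
}

#' Dependent t-test for paired samples
#'
#' Computed from first principles on the per-user differences:
#' `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1` degrees of freedom and a
#' two-sided p-value from the t distribution.
#'
#' @param deltas Numeric vector of paired differences; `n >= 2` and positive
#'   SD required.
#' @return One-row tibble: `t_statistic`, `df`, `p_value`, `mean_delta`,
#'   `sd_delta`, `n`.
#' @export
paired_t_test <- function(deltas) {
  n <- length(deltas)
  if (n < 2L) stop("paired_t_test: need at least 2 pairs", call. = FALSE)
  s <- sd(deltas)
  if (!is.finite(s) || s == 0) {
    stop("paired_t_test: zero variance in differences (degenerate test)",
         call. = FALSE)
  }
  m <- mean(deltas)
  t_stat <- m / (s / sqrt(n))
  df <- n - 1L
  tibble::tibble(
    t_statistic = t_stat,
    df = df,
    p_value = 2 * pt(-abs(t_stat), df),
    mean_delta = m,
    sd_delta = s,
    n = n
  )
}

#' Paired pre/post cohort comparison
#'
#' Joins two per-user metric tables (from [compute_window_metrics()]) on
#' `user_id`, computes per-user changes in TIR, mean glucose and GMI,
#' classifies TIR changes against the meaningful-change threshold, and runs
#' the dependent t-test on the paired TIR differences. Users present in only
#' one window are dropped from the pairing (count reported via [message()]).
#' "Improved" means a strictly positive TIR change; ties count as not
#' improved.
#'
#' @param pre,post Metric tibbles for the two windows, keyed by `user_id`.
#' @param threshold Meaningful-change threshold in TIR points.
#' @return Object of class `cgm_comparison`; see [tidy.cgm_comparison()] for
#'   per-user changes and [glance.cgm_comparison()] for the one-row cohort
#'   summary.
#' @export
summarize_comparison <- function(pre, post, threshold = 5) {
  needed <- c("user_id", "tir", "mean_glucose", "gmi",
              "meets_tir_goal", "meets_tar250_goal")
  stopifnot(all(needed %in% names(pre)), all(needed %in% names(post)))
  paired <- dplyr::inner_join(
    pre, post,
    by = "user_id", suffix = c("_pre", "_post")
  )
  n_dropped <- dplyr::n_distinct(c(pre$user_id, post$user_id)) - nrow(paired)
  if (nrow(paired) == 0L) {
    stop("summarize_comparison: no users present in both windows", call. = FALSE)
  }
  if (n_dropped > 0L) {
    message(sprintf(
      "summarize_comparison: %d user(s) missing one window were excluded from pairing",
      n_dropped
    ))
  }
  changes <- paired |>
    dplyr::transmute(
      user_id = .data$user_id,
      tir_pre = .data$tir_pre,
      tir_post = .data$tir_post,
      delta_tir = .data$tir_post - .data$tir_pre,
      delta_mean_glucose = .data$mean_glucose_post - .data$mean_glucose_pre,
      delta_gmi = .data$gmi_post - .data$gmi_pre,
      category = classify_change(.data$delta_tir, threshold)
    )
  # Degenerate pairing (zero variance, e.g. post identical to pre) keeps the
  # descriptive summary but reports an NA test.
  test <- if (nrow(changes) >= 2L && sd(changes$delta_tir) > 0) {
    paired_t_test(changes$delta_tir)
  } else {
    message("summarize_comparison: zero variance in TIR changes; t-test undefined")
    tibble::tibble(t_statistic = NA_real_, df = nrow(changes) - 1L,
                   p_value = NA_real_)
  }
  summary <- tibble::tibble(
    n = nrow(changes),
    tir_pre_mean = mean(paired$tir_pre),
    tir_pre_sd = sd(paired$tir_pre),
    tir_post_mean = mean(paired$tir_post),
    tir_post_sd = sd(paired$tir_post),
    mean_glucose_pre_mean = mean(paired$mean_glucose_pre),
    mean_glucose_pre_sd = sd(paired$mean_glucose_pre),
    mean_glucose_post_mean = mean(paired$mean_glucose_post),
    mean_glucose_post_sd = sd(paired$mean_glucose_post),
    gmi_pre_mean = mean(paired$gmi_pre),
    gmi_pre_sd = sd(paired$gmi_pre),
    gmi_post_mean = mean(paired$gmi_post),
    gmi_post_sd = sd(paired$gmi_post),
    delta_tir_mean = mean(changes$delta_tir),
    delta_tir_sd = sd(changes$delta_tir),
    delta_mean_glucose_mean = mean(changes$delta_mean_glucose),
    fraction_improved = mean(changes$delta_tir > 0),
    fraction_meaningful_increase = mean(changes$category == "meaningful_increase"),
    fraction_meaningful_decrease = mean(changes$category == "meaningful_decrease"),
    tir_goal_pre = mean(paired$meets_tir_goal_pre),
    tir_goal_post = mean(paired$meets_tir_goal_post),
    tar250_goal_pre = mean(paired$meets_tar250_goal_pre),
    tar250_goal_post = mean(paired$meets_tar250_goal_post),
    t_statistic = test$t_statistic,
    df = test$df,
    p_value = test$p_value
  )
  structure(
    list(changes = changes, summary = summary, threshold = threshold),
    class = "cgm_comparison"
  )
}

#' @export
print.cgm_comparison <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0(
      "<cgm_comparison: %d paired users>\n",
      "  TIR: %.1f (%.1f)%% -> %.1f (%.1f)%%, change %.1f (%.1f) points\n",
      "  improved (delta > 0): %.1f%%; meaningful +/-%g: %.1f%% up, %.1f%% down\n",
      "  paired t = %.2f, df = %d, p = %.3g\n"
    ),
    s$n, s$tir_pre_mean, s$tir_pre_sd, s$tir_post_mean, s$tir_post_sd,
    s$delta_tir_mean, s$delta_tir_sd,
    100 * s$fraction_improved, x$threshold,
    100 * s$fraction_meaningful_increase, 100 * s$fraction_meaningful_decrease,
    s$t_statistic, s$df, s$p_value
  ))
  invisible(x)
}

#' Per-user paired changes
#'
#' @param x A `cgm_comparison` object.
#' @param ... Unused.
#' @return Tibble with one row per paired user: pre/post TIR, changes in
#'   TIR, mean glucose and GMI, and the meaningful-change `category`.
#' @method tidy cgm_comparison
#' @export
tidy.cgm_comparison <- function(x, ...) {
  x$changes
}

#' One-row cohort comparison summary
#'
#' @param x A `cgm_comparison` object.
#' @param ... Unused.
#' @return One-row tibble with cohort means/SDs for both windows, the change
#'   distribution, classification fractions, goal-attainment fractions, and
#'   the paired t-test.
#' @method glance cgm_comparison
#' @export
glance.cgm_comparison <- function(x, ...) {
  x$summary
}

#' TIR histogram
#'
#' Bins per-user TIR values over \[0, 100\] with left-closed, right-open bins
#' (the terminal bin is closed on both ends so 100% is counted). If a
#' `window` column is present the histogram is computed per window, which
#' reproduces the overlaid pre/post distribution display.
#'
#' @param metrics Tibble with a `tir` column (optionally `window`).
#' @param bin_width Bin width in TIR points; must divide 100.
#' @return Tibble `window` (if given), `bin_left`, `bin_right`, `count`.
#' @export
tir_histogram <- function(metrics, bin_width = 2.5) {
  stopifnot("tir" %in% names(metrics), bin_width > 0)
  n_bins <- round(100 / bin_width)
  if (abs(n_bins * bin_width - 100) > 1e-9) {
    stop("tir_histogram: bin_width must divide 100", call. = FALSE)
  }
  lefts <- bin_width * (seq_len(n_bins) - 1L)
  one <- function(tir) {
    idx <- pmin(floor(tir / bin_width) + 1L, n_bins) # terminal bin absorbs 100
    tibble::tibble(
      bin_left = lefts,
      bin_right = lefts + bin_width,
      count = tabulate(idx, nbins = n_bins)
    )
  }
  if ("window" %in% names(metrics)) {
    metrics |>
      dplyr::group_by(.data$window) |>
      dplyr::reframe(one(.data$tir))
  } else {
    one(metrics$tir)
  }
}

#' Weekly mean trajectory of a glycemic metric
#'
#' For each 7-day week (anchored at `start_date`) and each group, the metric
#' is computed per user from that user's readings in the week, then averaged
#' across users; the spread is the standard error of the mean (SD/sqrt(n)).
#' Users with no readings in a week are omitted from that week's `n`; for
#' CV, users with fewer than 2 readings in the week are omitted. A group-week
#' with a single contributing user reports `sem = 0` with a warning.
#'
#' @param streams Long stream tibble.
#' @param users User metadata; required when `group_by` is used.
#' @param metric One of `"tir"`, `"mean_glucose"`, `"cv"`, `"tar250"`,
#'   `"tbr54"`.
#' @param start_date First day of the first week.
#' @param n_weeks Number of consecutive weeks.
#' @param group_by Optional metadata column name to stratify by (e.g.
#'   `"county_fips"` or `"region"`); `NULL` pools all users.
#' @param thresholds A [metric_thresholds()] object.
#' @return Tibble `group` (if requested), `week_start`, `n`, `mean`, `sem`.
#' @export
weekly_trajectory <- function(streams, users = NULL,
                              metric = c("tir", "mean_glucose", "cv",
                                         "tar250", "tbr54"),
                              start_date, n_weeks,
                              group_by = NULL,
                              thresholds = metric_thresholds()) {
  metric <- match.arg(metric)
  start_date <- as.Date(start_date)
  th <- thresholds
  metric_fun <- switch(
    metric,
    tir = function(g) pct_in_band(g, th$tir_low, th$tir_high),
    mean_glucose = mean,
    cv = function(g) if (length(g) >= 2L) compute_cv(g) else NA_real_,
    tar250 = function(g) pct_in_band(g, th$tar_level2, Inf,
                                     low_inclusive = FALSE),
    tbr54 = function(g) pct_in_band(g, -Inf, th$tbr_level2,
                                    high_inclusive = FALSE)
  )
  end_excl <- start_date + 7L * n_weeks
  per_user <- streams |>
    dplyr::mutate(day = utc_day(.data$timestamp)) |>
    dplyr::filter(.data$day >= .env$start_date, .data$day < .env$end_excl) |>
    dplyr::mutate(
      week_start = .env$start_date +
        7L * (as.integer(.data$day - .env$start_date) %/% 7L)
    ) |>
    dplyr::group_by(.data$user_id, .data$week_start) |>
    dplyr::summarise(value = metric_fun(.data$glucose), .groups = "drop") |>
    dplyr::filter(!is.na(.data$value))
  if (!is.null(group_by)) {
    stopifnot(!is.null(users), group_by %in% names(users))
    per_user <- per_user |>
      dplyr::left_join(
        dplyr::select(users, "user_id", group = dplyr::all_of(group_by)),
        by = "user_id"
      )
    grouping <- c("group", "week_start")
  } else {
    grouping <- "week_start"
  }
  out <- per_user |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sem = if (dplyr::n() >= 2L) sd(.data$value) / sqrt(dplyr::n()) else 0,
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(grouping)))
  if (any(out$n == 1L)) {
    warning("weekly_trajectory: SEM reported as 0 for week(s) with n = 1",
            call. = FALSE)
  }
  out
}
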