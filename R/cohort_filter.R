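#' Data-density rule
#'
#' The study's wear-time requirement: at least `min_readings_per_day` sensor
#' values per day on at least `min_days_per_week` days per week, in both
#' observation windows. `scope` controls how "per week" is read: `"per_week"`
#' (default) requires every 7-day week of the window to qualify on its own;
#' `"per_window"` requires only the equivalent total number of qualifying days
#' across the window. Setting `enabled = FALSE` disables the density check
#' entirely (the relaxed variant used for the late-summer window).
#'
#' @param min_readings_per_day Minimum readings for a day to qualify.
#' @param min_days_per_week Minimum qualifying days per week.
#' @param enabled If `FALSE`, [passes_density()] is always `TRUE`.
#' @param scope `"per_week"` or `"per_window"`.
#' @return A list of class `density_rule`.
#' @export
density_rule <- function(min_readings_per_day = 200L, min_days_per_week = 4L,
                         enabled = TRUE, scope = c("per_week", "per_window")) {
  scope <- match.arg(scope)
  stopifnot(
    min_readings_per_day >= 0L, min_days_per_week >= 0L,
    min_days_per_week <= 7L, is.logical(enabled)
  )
  structure(
    list(
      min_readings_per_day = as.integer(min_readings_per_day),
      min_days_per_week = as.integer(min_days_per_week),
      enabled = enabled, scope = scope
    ),
    class = "density_rule"
  )
}

#' Per-day reading counts within a window
#'
#' Every calendar day of the window is present for every user in `streams`
#' (zero-filled), so gap days are explicit.
#'
#' @param streams Long stream tibble (`user_id`, `timestamp`, `glucose`).
#' @param window An [observation_window()].
#' @return Tibble `user_id`, `day` (Date), `n` (reading count, >= 0), with
#'   `length(window_days(window))` rows per user.
#' @export
daily_counts <- function(streams, window) {
  users <- unique(streams$user_id)
  days <- window_days(window)
  grid <- tidyr::expand_grid(user_id = users, day = days)
  clipped <- window_clip(streams, window)
  counts <- clipped |>
    dplyr::mutate(day = utc_day(.data$timestamp)) |>
    dplyr::count(.data$user_id, .data$day)
  grid |>
    dplyr::left_join(counts, by = c("user_id", "day")) |>
    dplyr::mutate(n = tidyr::replace_na(.data$n, 0L)) |>
    dplyr::arrange(.data$user_id, .data$day)
}

#' Density-rule check per user
#'
#' A day qualifies when it has at least `rule$min_readings_per_day` readings.
#' Under `scope = "per_week"`, a user passes when every 7-day week of the
#' window (weeks anchored at the window start date) has at least
#' `rule$min_days_per_week` qualifying days; under `"per_window"`, when the
#' window total of qualifying days reaches
#' `min_days_per_week * n_weeks`. A disabled rule passes everyone.
#'
#' @param streams Long stream tibble.
#' @param window An [observation_window()].
#' @param rule A [density_rule()].
#' @return Tibble `user_id`, `passes` (logical), one row per user in
#'   `streams`.
#' @export
passes_density <- function(streams, window, rule = density_rule()) {
  stopifnot(inherits(rule, "density_rule"))
  users <- unique(streams$user_id)
  if (!rule$enabled) {
    return(tibble::tibble(user_id = users, passes = TRUE))
  }
  dc <- daily_counts(streams, window)
  dc$week <- (as.integer(dc$day - window$start_date) %/% 7L) + 1L
  per_week <- dc |>
    dplyr::group_by(.data$user_id, .data$week) |>
    dplyr::summarise(
      qualifying = sum(.data$n >= rule$min_readings_per_day),
      .groups = "drop"
    )
  verdict <- if (rule$scope == "per_week") {
    per_week |>
      dplyr::group_by(.data$user_id) |>
      dplyr::summarise(
        passes = all(.data$qualifying >= rule$min_days_per_week),
        .groups = "drop"
      )
  } else {
    per_week |>
      dplyr::group_by(.data$user_id) |>
      dplyr::summarise(
        passes = sum(.data$qualifying) >=
          rule$min_days_per_week * window$n_weeks,
        .groups = "drop"
      )
  }
  verdict[match(users, verdict$user_id), ]
}

#' First-half-of-2020 monthly presence check
#'
#' `TRUE` for a user iff every listed calendar month contains at least one
#' reading.
#'
#' @param streams Long stream tibble.
#' @param months Vector of first-of-month dates; defaults to January--June
#'   2020.
#' @return Tibble `user_id`, `present` (logical).
#' @export
monthly_presence <- function(streams,
                             months = seq(as.Date("2020-01-01"),
                                          as.Date("2020-06-01"), by = "month")) {
  months <- lubridate::floor_date(as.Date(months), "month")
  users <- unique(streams$user_id)
  seen <- streams |>
    dplyr::mutate(
      month = lubridate::floor_date(utc_day(.data$timestamp), "month")
    ) |>
    dplyr::filter(.data$month %in% .env$months) |>
    dplyr::distinct(.data$user_id, .data$month) |>
    dplyr::count(.data$user_id, name = "n_months")
  tibble::tibble(user_id = users) |>
    dplyr::left_join(seen, by = "user_id") |>
    dplyr::mutate(
      present = tidyr::replace_na(.data$n_months, 0L) == length(.env$months)
    ) |>
    dplyr::select("user_id", "present")
}

#' Apply the study inclusion criteria to a cohort
#'
#' A user is included iff all of:
#' \itemize{
#'   \item started using the system on or before `start_cutoff`
#'     (`first_upload <= start_cutoff`, inclusive) — else `late_start`;
#'   \item used the mobile app — else `not_mobile`;
#'   \item uploaded at least one value in every month January--June 2020 —
#'     else `missing_month`;
#'   \item passes the density rule in the prepandemic window — else
#'     `density_pre`;
#'   \item passes it in the intrapandemic window — else `density_post`.
#' }
#' Users absent from `streams` fail the stream-based criteria. A report row
#' is emitted for every user; `passed` is `TRUE` exactly when
#' `failure_reasons` is empty.
#'
#' @param users User metadata tibble (needs `user_id`, `first_upload`,
#'   `mobile_app`).
#' @param streams Long stream tibble.
#' @param pre_window,post_window [observation_window()]s.
#' @param rule A [density_rule()].
#' @param start_cutoff Latest admissible first-upload date.
#' @param months Months for the presence check (see [monthly_presence()]).
#' @return List with `included` (subset of `users`) and `reports` (tibble
#'   `user_id`, `passed`, `failure_reasons` list-column, `reasons` as a
#'   comma-joined string).
#' @export
filter_cohort <- function(users, streams, pre_window, post_window,
                          rule = density_rule(),
                          start_cutoff = as.Date("2020-01-01"),
                          months = seq(as.Date("2020-01-01"),
                                       as.Date("2020-06-01"), by = "month")) {
  stopifnot(all(c("user_id", "first_upload", "mobile_app") %in% names(users)))
  lookup <- function(tbl, col, default) {
    v <- tbl[[col]][match(users$user_id, tbl$user_id)]
    v[is.na(v)] <- default
    v
  }
  mp <- monthly_presence(streams, months)
  dpre <- passes_density(streams, pre_window, rule)
  dpost <- passes_density(streams, post_window, rule)

  assemble_inclusion(
    users,
    monthly_ok = lookup(mp, "present", FALSE),
    density_pre_ok = lookup(dpre, "passes", !rule$enabled),
    density_post_ok = lookup(dpost, "passes", !rule$enabled),
    start_cutoff = start_cutoff
  )
}

# Build inclusion reports from per-user criterion verdicts (aligned with
# `users` rows).
assemble_inclusion <- function(users, monthly_ok, density_pre_ok,
                               density_post_ok, start_cutoff) {
  fail <- tibble::tibble(
    late_start = users$first_upload > as.Date(start_cutoff),
    not_mobile = !users$mobile_app,
    missing_month = !monthly_ok,
    density_pre = !density_pre_ok,
    density_post = !density_post_ok
  )
  reasons <- apply(as.matrix(fail), 1L, function(r) names(fail)[r],
                   simplify = FALSE)
  reports <- tibble::tibble(
    user_id = users$user_id,
    passed = lengths(reasons) == 0L,
    failure_reasons = reasons,
    reasons = vapply(reasons, paste, character(1L), collapse = ",")
  )
  list(
    included = users[reports$passed, ],
    reports = reports
  )
}
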