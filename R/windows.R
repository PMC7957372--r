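#' Observation windows
#'
#' An observation window is a named, closed date interval whose length is an
#' exact multiple of 7 days, so it partitions cleanly into consecutive weeks
#' anchored at the start date. The canonical study windows (see
#' [paper_windows()]) start on a Monday, so window weeks coincide with
#' calendar Mon--Sun weeks.
#'
#' @param label Short name for the window (e.g. `"prepandemic"`).
#' @param start_date,end_date Inclusive bounds, coercible with [as.Date()].
#'
#' @return An object of class `obs_window`: a list with `label`, `start_date`,
#'   `end_date`, and `n_weeks`.
#' @examples
#' w <- observation_window("prepandemic", "2020-01-06", "2020-03-01")
#' w$n_weeks # 8
#' @export
observation_window <- function(label, start_date, end_date) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  stopifnot(is.character(label), length(label) == 1L)
  if (is.na(start_date) || is.na(end_date)) {
    stop("observation_window: unparseable start or end date", call. = FALSE)
  }
  n_days <- as.integer(end_date - start_date) + 1L
  if (n_days <= 0L) {
    stop("observation_window: end_date precedes start_date", call. = FALSE)
  }
  if (n_days %% 7L != 0L) {
    stop(
      sprintf(
        "observation_window '%s': %d days is not a whole number of weeks",
        label, n_days
      ),
      call. = FALSE
    )
  }
  structure(
    list(
      label = label, start_date = start_date, end_date = end_date,
      n_weeks = n_days %/% 7L
    ),
    class = "obs_window"
  )
}

#' @export
print.obs_window <- function(x, ...) {
  cat(sprintf(
    "<obs_window '%s': %s .. %s (%d weeks)>\n",
    x$label, format(x$start_date), format(x$end_date), x$n_weeks
  ))
  invisible(x)
}

#' Week grid of an observation window
#'
#' @param window An [observation_window()].
#' @return A tibble with one row per 7-day week: `week` (1-based index),
#'   `week_start`, `week_end` (inclusive dates).
#' @export
window_weeks <- function(window) {
  stopifnot(inherits(window, "obs_window"))
  starts <- window$start_date + 7L * (seq_len(window$n_weeks) - 1L)
  tibble::tibble(
    week = seq_len(window$n_weeks),
    week_start = starts,
    week_end = starts + 6L
  )
}

#' All calendar days of an observation window
#' @param window An [observation_window()].
#' @return A `Date` vector covering the window, inclusive.
#' @export
window_days <- function(window) {
  stopifnot(inherits(window, "obs_window"))
  seq(window$start_date, window$end_date, by = "day")
}

#' The study's canonical observation windows
#'
#' Three 8-week windows: the prepandemic interval (Jan 6 -- Mar 1, 2020), the
#' early intrapandemic interval (Apr 20 -- Jun 14, 2020), and a later
#' intrapandemic interval (Jun 15 -- Aug 9, 2020) used with relaxed
#' data-density requirements.
#'
#' @return Named list of [observation_window()] objects
#'   (`pre`, `post`, `late`).
#' @export
paper_windows <- function() {
  list(
    pre = observation_window("prepandemic", "2020-01-06", "2020-03-01"),
    post = observation_window("intrapandemic", "2020-04-20", "2020-06-14"),
    late = observation_window("late_intrapandemic", "2020-06-15", "2020-08-09")
  )
}

# Fast UTC calendar day of a POSIXct vector (avoids POSIXlt conversion).
utc_day <- function(ts) {
  as.Date(floor(as.numeric(ts) / 86400), origin = "1970-01-01")
}

# Restrict a long-format stream table to a window (closed on calendar days,
# evaluated in UTC).
window_clip <- function(streams, window) {
  stopifnot(inherits(window, "obs_window"))
  lo <- as.POSIXct(paste(window$start_date, "00:00:00"), tz = "UTC")
  hi <- as.POSIXct(paste(window$end_date + 1L, "00:00:00"), tz = "UTC")
  dplyr::filter(streams, .data$timestamp >= lo, .data$timestamp < hi)
}
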