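# Builders for small in-memory stream fixtures (all timestamps UTC).

utc <- function(x) as.POSIXct(x, tz = "UTC")

# n readings on a given day at the 5-minute cadence, constant or supplied
# glucose values
day_slots <- function(user_id, day, n = 288L, glucose = 120L) {
  start <- utc(paste(as.Date(day), "00:00:00"))
  tibble::tibble(
    user_id = user_id,
    timestamp = start + 300 * (seq_len(n) - 1L),
    glucose = as.integer(rep_len(glucose, n))
  )
}

# a stream covering several days with a per-day reading count
multi_day_stream <- function(user_id, days, per_day = 288L, glucose = 120L) {
  per_day <- rep_len(per_day, length(days))
  dplyr::bind_rows(lapply(seq_along(days), function(i) {
    if (per_day[i] == 0L) return(NULL)
    day_slots(user_id, days[i], per_day[i], glucose)
  }))
}

# a fully compliant stream for the canonical study windows plus one reading
# in each remaining month of Jan-Jun 2020
compliant_stream <- function(user_id, windows = paper_windows(),
                             per_day = 288L, glucose = 120L) {
  dplyr::bind_rows(
    multi_day_stream(user_id, window_days(windows$pre), per_day, glucose),
    multi_day_stream(user_id, window_days(windows$post), per_day, glucose),
    day_slots(user_id, "2020-03-15", 1L, glucose) # March beyond window end
  )
}

# metric-table row builder for comparison tests that do not need streams
metric_row <- function(user_id, tir, mean_glucose = 150, window = "w") {
  tibble::tibble(
    user_id = user_id, window = window, n_readings = 100L,
    tir = tir, tbr54 = 0, tbr70 = 0, tar180 = 100 - tir, tar250 = 0,
    mean_glucose = mean_glucose, sd_glucose = 10,
    cv = 100 * 10 / mean_glucose, gmi = compute_gmi(mean_glucose),
    meets_tir_goal = tir >= 70, meets_tar250_goal = TRUE
  )
}
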