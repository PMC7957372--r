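#' @importFrom rlang .data .env
#' @importFrom stats sd rnorm rlnorm runif rgamma pt
#' @importFrom utils head
NULL

# Sensor-reportable glucose range (mg/dL). Out-of-range rows are dropped at
# ingest, never clamped, so the drop count is auditable.
GLUCOSE_MIN <- 40L
GLUCOSE_MAX <- 400L

# Lenient ISO-8601 parsing to UTC; unmatched strings become NA per element
# (no hard error), so callers can report offending line numbers.
parse_iso_instant <- function(x) {
  fmts <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d")
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  for (f in fmts) {
    idx <- which(is.na(out))
    if (length(idx) == 0L) break
    out[idx] <- as.POSIXct(strptime(x[idx], f, tz = "UTC"))
  }
  out
}

#' Read per-user CGM streams from CSV
#'
#' Expects a header `user_id,timestamp,glucose` with ISO-8601 timestamps and
#' integer glucose in mg/dL. Rows are sorted by user and time; duplicate
#' `(user_id, timestamp)` rows collapse to the first occurrence; rows with
#' glucose outside the sensor-reportable range \[40, 400\] mg/dL are dropped.
#' Both drop counts are reported with [message()].
#'
#' Timestamps are parsed as UTC instants; all downstream day and week
#' boundaries are evaluated in a single reference timezone (UTC), which keeps
#' day boundaries deterministic for a cohort spanning several US timezones.
#'
#' @param path CSV file path.
#' @return A tibble with columns `user_id` (character), `timestamp` (POSIXct,
#'   UTC), `glucose` (integer), ordered by user then time.
#' @export
read_glucose_csv <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      user_id = readr::col_character(),
      timestamp = readr::col_character(),
      glucose = readr::col_double()
    )
  )
  required <- c("user_id", "timestamp", "glucose")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop(
      sprintf("glucose CSV missing column(s): %s", paste(missing, collapse = ", ")),
      call. = FALSE
    )
  }
  ts <- parse_iso_instant(raw$timestamp)
  bad <- which(is.na(ts) & !is.na(raw$timestamp))
  if (length(bad) > 0L) {
    stop(
      sprintf(
        "unparseable timestamp(s) at data line(s): %s",
        paste(head(bad, 10L), collapse = ", ")
      ),
      call. = FALSE
    )
  }
  out <- tibble::tibble(
    user_id = raw$user_id,
    timestamp = ts,
    glucose = as.integer(raw$glucose)
  )
  in_range <- out$glucose >= GLUCOSE_MIN & out$glucose <= GLUCOSE_MAX
  n_range_dropped <- sum(!in_range)
  out <- out[in_range, ]
  out <- dplyr::arrange(out, .data$user_id, .data$timestamp)
  dup <- duplicated(out[, c("user_id", "timestamp")])
  n_dup_dropped <- sum(dup)
  out <- out[!dup, ]
  if (n_range_dropped > 0L) {
    message(sprintf(
      "read_glucose_csv: dropped %d row(s) with glucose outside [%d, %d] mg/dL",
      n_range_dropped, GLUCOSE_MIN, GLUCOSE_MAX
    ))
  }
  if (n_dup_dropped > 0L) {
    message(sprintf(
      "read_glucose_csv: collapsed %d duplicate (user, timestamp) row(s)",
      n_dup_dropped
    ))
  }
  out
}

#' Write CGM streams to CSV
#'
#' Inverse of [read_glucose_csv()]: writing then reading a valid stream table
#' round-trips exactly.
#'
#' @param streams Tibble with `user_id`, `timestamp` (POSIXct UTC), `glucose`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_glucose_csv <- function(streams, path) {
  out <- tibble::tibble(
    user_id = streams$user_id,
    timestamp = format(streams$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    glucose = as.integer(streams$glucose)
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Read user metadata CSV
#'
#' Schema: `user_id,zip,county_fips,state,median_income,first_upload,
#' last_upload,mobile_app`. Adds `tenure_months` (whole months between first
#' and last upload) and `region` (via [assign_region()]).
#'
#' @param path CSV path.
#' @param region_map Optional state-to-region table; defaults to
#'   [cdc_region_map()].
#' @return Tibble of user records.
#' @export
read_user_metadata <- function(path, region_map = cdc_region_map()) {
  users <- readr::read_csv(
    path,
    col_types = readr::cols(
      user_id = readr::col_character(),
      zip = readr::col_character(),
      county_fips = readr::col_character(),
      state = readr::col_character(),
      median_income = readr::col_double(),
      first_upload = readr::col_date(),
      last_upload = readr::col_date(),
      mobile_app = readr::col_logical()
    )
  )
  required <- c(
    "user_id", "zip", "county_fips", "state", "median_income",
    "first_upload", "last_upload", "mobile_app"
  )
  missing <- setdiff(required, names(users))
  if (length(missing) > 0L) {
    stop(
      sprintf("user metadata missing column(s): %s", paste(missing, collapse = ", ")),
      call. = FALSE
    )
  }
  users$tenure_months <- tenure_months(users$first_upload, users$last_upload)
  users$region <- assign_region(users$state, region_map)
  users
}

#' Whole months between two dates
#'
#' Tenure with the device is the number of whole calendar months between the
#' first and most recent upload, floored at 0.
#'
#' @param first,last Date vectors.
#' @return Integer vector of whole months, `>= 0`.
#' @export
tenure_months <- function(first, last) {
  iv <- lubridate::interval(as.Date(first), as.Date(last))
  m <- iv %/% months(1)
  as.integer(pmax(m, 0L))
}

#' Read a county COVID-19 burden table (NYT schema)
#'
#' The input follows the NYT covid-19-data county schema
#' `date,county,state,fips,cases,deaths` with cumulative counts. For each
#' FIPS, the row with the latest date at or before `as_of` is returned; a
#' FIPS with no row at or before `as_of` is omitted (count reported via
#' [message()]).
#'
#' @param path CSV path.
#' @param as_of Cutoff date (default the study's May 21, 2020 snapshot).
#' @return Tibble with one row per FIPS: `fips`, `county`, `state`, `date`,
#'   `cases`, `deaths`.
#' @export
read_county_burden <- function(path, as_of = as.Date("2020-05-21")) {
  as_of <- as.Date(as_of)
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      date = readr::col_date(),
      county = readr::col_character(),
      state = readr::col_character(),
      fips = readr::col_character(),
      cases = readr::col_double(),
      deaths = readr::col_double()
    )
  )
  required <- c("date", "county", "state", "fips", "cases", "deaths")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop(
      sprintf("county burden CSV missing column(s): %s", paste(missing, collapse = ", ")),
      call. = FALSE
    )
  }
  all_fips <- unique(raw$fips)
  out <- raw |>
    dplyr::filter(.data$date <= .env$as_of) |>
    dplyr::group_by(.data$fips) |>
    dplyr::slice_max(.data$date, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("fips", "county", "state", "date", "cases", "deaths")
  omitted <- setdiff(all_fips, out$fips)
  if (length(omitted) > 0L) {
    message(sprintf(
      "read_county_burden: %d county(ies) had no row on or before %s and were omitted",
      length(omitted), format(as_of)
    ))
  }
  out
}

#' State-to-region map for the five CDC Centers of Excellence regions
#'
#' The five regions are named for their hub states (Colorado, Minnesota,
#' New York, Tennessee, Washington) and jointly cover the 50 states, DC and
#' the territories. The packaged table is a synthetic reconstruction: hubs and
#' per-region state counts match the published description, but the exact
#' membership of non-hub states is approximated by geography (the authoritative
#' table is not redistributed here).
#'
#' @return Tibble with columns `state` (2-letter code) and `region`.
#' @export
cdc_region_map <- function() {
  path <- system.file("extdata", "region_map_synthetic.csv", package = "cgmtrends")
  readr::read_csv(
    path,
    comment = "#",
    col_types = readr::cols(
      state = readr::col_character(),
      region = readr::col_character()
    )
  )
}

#' Assign states to CDC regions
#'
#' Total function: any state code absent from the map yields `"unassigned"`.
#'
#' @param state Character vector of 2-letter state codes.
#' @param region_map Table with `state` and `region` columns; defaults to
#'   [cdc_region_map()].
#' @return Character vector of region labels.
#' @export
assign_region <- function(state, region_map = cdc_region_map()) {
  idx <- match(state, region_map$state)
  out <- region_map$region[idx]
  out[is.na(idx)] <- "unassigned"
  out
}

#' FIPS codes of the five counties comprising New York City
#'
#' New York City is modeled as the union of its five county FIPS codes
#' (New York, Kings, Queens, Bronx, Richmond).
#'
#' @return Character vector of five FIPS codes.
#' @export
nyc_fips <- function() {
  c("36061", "36047", "36081", "36005", "36085")
}
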