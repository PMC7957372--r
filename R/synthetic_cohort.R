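#' Synthetic cohort generator configuration
#'
#' Parameters of the generative model used to emulate the statistical
#' structure of a large real-time CGM uploader population. Within a user,
#' glucose is lognormal around the user's mean with AR(1) dependence between
#' consecutive 5-minute readings; between users, mean glucose varies normally
#' and is tilted by zip-level income; the pandemic acts as a step change in
#' each user's mean glucose at the stay-at-home date, with a county component
#' coupled to log COVID-19 deaths.
#'
#' Defaults are calibrated once against the published population statistics
#' of the study cohort (prepandemic mean glucose 173.3 mg/dL with SD 35.9
#' across users; mean TIR near 59% with SD near 20; paired TIR change near
#' +2.0 points with SD near 10; mean glucose shift -3.1 mg/dL) and then
#' frozen; see the methods vignette.
#'
#' @param n_users Number of users.
#' @param n_counties Number of counties.
#' @param seed Integer seed; all generator randomness flows from it.
#' @param pop_mean_glucose Population mean of user mean glucose, mg/dL.
#' @param between_user_sd SD of user mean glucose around the population mean
#'   (residual of the income gradient), mg/dL.
#' @param within_user_sd Within-user SD of readings, mg/dL, for a user at
#'   the population mean glucose. Within-user coefficient of variation is
#'   constant across users (`within_user_sd / pop_mean_glucose`), so the SD
#'   in mg/dL scales with each user's mean; internally this is a lognormal
#'   log-scale SD preserving the user's arithmetic mean.
#' @param ar1_rho AR(1) coefficient of consecutive 5-minute log-residuals,
#'   in \[0, 1).
#' @param pandemic_shift_mean Mean step change in user mean glucose at the
#'   pandemic onset, mg/dL (negative = improvement).
#' @param pandemic_shift_sd Between-user SD of the step change, mg/dL.
#' @param burden_coupling Effect (mg/dL per SD) of a county's standardized
#'   log deaths on its users' glucose shift; positive coupling lowers glucose
#'   (improves TIR) in high-burden counties.
#' @param income_gradient Effect (mg/dL per SD) of standardized log zip
#'   income on baseline mean glucose (higher income, lower glucose).
#' @param income_gradient_shift Effect (mg/dL per SD) of standardized log
#'   income on the pandemic shift (higher income, larger improvement).
#' @param cv_shift_coupling Unitless coupling of a user's glucose shift to
#'   their within-user variability: a shift of `x` mg/dL scales the user's
#'   CV by `1 + cv_shift_coupling * x / pop_mean_glucose` in the shifted
#'   period. A positive value makes improvements reduce variability, which
#'   concentrates TIR gains in the hyperglycemic tail (as observed in
#'   population CGM data) rather than trading them against hypoglycemia.
#' @param daily_dropout_prob Probability a calendar day has no data.
#' @param within_day_missing_frac Fraction of 5-minute slots missing on
#'   observed days.
#' @param p_mobile Probability a user views data on the mobile app.
#' @param p_late_start Probability a user first uploaded after Jan 1, 2020.
#' @param pandemic_onset Date of the step change (stay-at-home orders).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_users = 2000L,
                             n_counties = 25L,
                             seed = 20200106L,
                             pop_mean_glucose = 173.3,
                             between_user_sd = 35.9,
                             within_user_sd = 55,
                             ar1_rho = 0.95,
                             pandemic_shift_mean = -3.1,
                             pandemic_shift_sd = 15,
                             cv_shift_coupling = 1,
                             burden_coupling = 2,
                             income_gradient = 3,
                             income_gradient_shift = 0.75,
                             daily_dropout_prob = 0.05,
                             within_day_missing_frac = 0.1,
                             p_mobile = 0.97,
                             p_late_start = 0.02,
                             pandemic_onset = as.Date("2020-03-19")) {
  cfg <- list(
    n_users = as.integer(n_users), n_counties = as.integer(n_counties),
    seed = as.integer(seed),
    pop_mean_glucose = pop_mean_glucose, between_user_sd = between_user_sd,
    within_user_sd = within_user_sd, ar1_rho = ar1_rho,
    pandemic_shift_mean = pandemic_shift_mean,
    pandemic_shift_sd = pandemic_shift_sd,
    cv_shift_coupling = cv_shift_coupling,
    burden_coupling = burden_coupling,
    income_gradient = income_gradient,
    income_gradient_shift = income_gradient_shift,
    daily_dropout_prob = daily_dropout_prob,
    within_day_missing_frac = within_day_missing_frac,
    p_mobile = p_mobile, p_late_start = p_late_start,
    pandemic_onset = as.Date(pandemic_onset)
  )
  stopifnot(
    cfg$n_users >= 0L, cfg$n_counties >= 1L,
    cfg$between_user_sd >= 0, cfg$within_user_sd >= 0,
    cfg$pandemic_shift_sd >= 0,
    cfg$ar1_rho >= 0, cfg$ar1_rho < 1,
    cfg$daily_dropout_prob >= 0, cfg$daily_dropout_prob <= 1,
    cfg$within_day_missing_frac >= 0, cfg$within_day_missing_frac <= 1,
    cfg$p_mobile >= 0, cfg$p_mobile <= 1,
    cfg$p_late_start >= 0, cfg$p_late_start <= 1
  )
  structure(cfg, class = "generator_config")
}

SLOTS_PER_DAY <- 288L # 5-minute cadence
SLOT_SECONDS <- 300

#' Generate a synthetic county table
#'
#' Counties get synthetic FIPS codes, states drawn from the region map (so
#' region assignment is exercised), log-normally distributed cumulative
#' deaths, a latent burden effect proportional to standardized log deaths
#' (scaled by `burden_coupling`), and skewed user-allocation weights so that
#' with realistic cohort sizes some counties exceed a 200-user floor and
#' others do not.
#'
#' Uses the current RNG state; seed via [set.seed()] or use
#' [generate_cohort()] which seeds from the config.
#'
#' @param config A [generator_config()].
#' @param as_of Snapshot date attached to the burden rows.
#' @return Tibble `fips`, `county`, `state`, `date`, `cases`, `deaths`,
#'   `user_weight`, `burden_effect`.
#' @export
generate_counties <- function(config, as_of = as.Date("2020-05-21")) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_counties
  states <- cdc_region_map()$state
  deaths <- round(rlnorm(n, meanlog = 3.5, sdlog = 1.6))
  log_d <- log(pmax(deaths, 1))
  z <- if (n >= 2L && sd(log_d) > 0) (log_d - mean(log_d)) / sd(log_d) else rep(0, n)
  tibble::tibble(
    fips = sprintf("90%03d", seq_len(n)),
    county = sprintf("Synth County %03d", seq_len(n)),
    state = sample(states, n, replace = TRUE),
    date = as_of,
    cases = deaths * 20L + round(rlnorm(n, meanlog = 4, sdlog = 1)),
    deaths = as.integer(deaths),
    user_weight = rgamma(n, shape = 0.6, rate = 1),
    # mg/dL added to the pandemic glucose shift; negative in high-burden
    # counties so improvement tracks burden
    burden_effect = -config$burden_coupling * z
  )
}

# AR(1) series with stationary N(0,1) marginals.
ar1_series <- function(n, rho) {
  if (n == 0L) return(numeric(0))
  if (rho == 0) return(rnorm(n))
  innov <- rnorm(n - 1L) * sqrt(1 - rho^2)
  as.numeric(stats::filter(c(rnorm(1L), innov), rho, method = "recursive"))
}

#' Generate one user's glucose stream
#'
#' Readings are produced at the 5-minute cadence over each window. The log
#' of glucose follows the user's (possibly shifted) mean plus AR(1) noise
#' with a stationary log-scale SD giving the configured within-user CV
#' (`within_user_sd / pop_mean_glucose`); whole days drop out with
#' `daily_dropout_prob` and individual slots with `within_day_missing_frac`;
#' rounded values are clamped into the sensor-reportable range \[40, 400\]
#' mg/dL. Slots on or after `config$pandemic_onset` use the shifted mean
#' `baseline_mean + shift` and a CV scaled by
#' `1 + cv_shift_coupling * shift / pop_mean_glucose`; slots before the
#' user's `first_upload` (if given in `params`) are dropped.
#'
#' Uses the current RNG state.
#'
#' @param params List or one-row data frame with `user_id`, `baseline_mean`
#'   (mg/dL), `shift` (mg/dL), and optionally `first_upload` (Date).
#' @param windows List of disjoint [observation_window()]s.
#' @param config A [generator_config()].
#' @return Stream tibble `user_id`, `timestamp` (POSIXct UTC), `glucose`.
#' @export
generate_user_stream <- function(params, windows, config) {
  stopifnot(inherits(config, "generator_config"))
  if (inherits(windows, "obs_window")) windows <- list(windows)
  onset_sec <- as.numeric(as.POSIXct(
    paste(config$pandemic_onset, "00:00:00"), tz = "UTC"
  ))
  first_sec <- if (!is.null(params$first_upload) && !is.na(params$first_upload)) {
    as.numeric(as.POSIXct(paste(as.Date(params$first_upload), "00:00:00"),
                          tz = "UTC"))
  } else {
    -Inf
  }
  pieces <- lapply(windows, function(w) {
    days <- window_days(w)
    nd <- length(days)
    n_slots <- nd * SLOTS_PER_DAY
    day0 <- as.numeric(as.POSIXct(paste(w$start_date, "00:00:00"), tz = "UTC"))
    secs <- day0 + SLOT_SECONDS * (seq_len(n_slots) - 1)
    day_kept <- runif(nd) >= config$daily_dropout_prob
    slot_kept <- runif(n_slots) >= config$within_day_missing_frac
    keep <- day_kept[rep(seq_len(nd), each = SLOTS_PER_DAY)] & slot_kept &
      secs >= first_sec
    z <- ar1_series(n_slots, config$ar1_rho)
    shifted <- secs >= onset_sec
    m <- ifelse(shifted, params$baseline_mean + params$shift,
                params$baseline_mean)
    m <- pmax(m, 1) # guard against pathological shifts
    base_cv <- config$within_user_sd / config$pop_mean_glucose
    cv_scale <- pmax(
      1 + config$cv_shift_coupling * params$shift / config$pop_mean_glucose,
      0.2
    )
    cv <- ifelse(shifted, base_cv * cv_scale, base_cv)
    s_log <- sqrt(log(1 + cv^2))
    mu_log <- log(m) - s_log^2 / 2
    glucose <- round(exp(mu_log + s_log * z))
    glucose <- pmin(pmax(glucose, GLUCOSE_MIN), GLUCOSE_MAX)
    list(secs = secs[keep], glucose = as.integer(glucose[keep]))
  })
  secs <- unlist(lapply(pieces, `[[`, "secs"), use.names = FALSE)
  glucose <- unlist(lapply(pieces, `[[`, "glucose"), use.names = FALSE)
  if (is.null(secs)) secs <- numeric(0)
  tibble::tibble(
    user_id = rep(as.character(params$user_id), length(secs)),
    timestamp = as.POSIXct(secs, origin = "1970-01-01", tz = "UTC"),
    glucose = as.integer(glucose)
  )
}

#' Generate a full synthetic cohort
#'
#' Produces the four tables the pipeline consumes: user metadata, long-format
#' glucose streams over the requested windows, the county burden table, and
#' the ground-truth parameter table used by recovery tests. Fully
#' reproducible: identical config (and seed) gives identical output.
#'
#' The generative structure, per user i in county c(i) with zip income
#' `inc(i)`:
#' \itemize{
#'   \item baseline mean glucose
#'     `m_i = pop_mean_glucose - income_gradient * z_inc(i) + N(0, between_user_sd)`;
#'   \item pandemic step shift
#'     `s_i = (m_i / pop_mean_glucose) * (pandemic_shift_mean +
#'     burden_effect(c(i)) - income_gradient_shift * z_inc(i) +
#'     N(0, pandemic_shift_sd))`, i.e. proportional in magnitude to the
#'     user's glucose level with expectation `pandemic_shift_mean`;
#'   \item readings lognormal around `m_i` (then `m_i + s_i` after the onset
#'     date) with AR(1) 5-minute residuals and configured missingness.
#' }
#' Tenure is drawn from a mixture spanning under a year to five years, so a
#' ">= 37 months" stratum always exists; a `p_late_start` fraction of users
#' first uploaded after Jan 1, 2020 and a `1 - p_mobile` fraction are
#' receiver-only, so the inclusion filters have work to do.
#'
#' @param config A [generator_config()].
#' @param windows List of [observation_window()]s to cover (default: the
#'   canonical pre and post windows).
#' @param seed Overrides `config$seed` when given.
#' @return List of class `synthetic_cohort` with `users`, `streams`,
#'   `counties`, `truth`, and the `config`.
#' @export
generate_cohort <- function(config = generator_config(),
                            windows = paper_windows()[c("pre", "post")],
                            seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(if (is.null(seed)) config$seed else as.integer(seed))
  frame <- cohort_frame(config)
  streams <- dplyr::bind_rows(lapply(seq_len(config$n_users), function(i) {
    generate_user_stream(
      list(user_id = frame$users$user_id[i],
           baseline_mean = frame$truth$baseline_mean[i],
           shift = frame$truth$shift[i],
           first_upload = frame$users$first_upload[i]),
      windows, config
    )
  }))
  if (nrow(streams) == 0L) {
    streams <- tibble::tibble(
      user_id = character(0),
      timestamp = as.POSIXct(character(0), tz = "UTC"),
      glucose = integer(0)
    )
  }
  structure(
    list(users = frame$users, streams = streams, counties = frame$counties,
         truth = frame$truth, config = config),
    class = "synthetic_cohort"
  )
}

# Draws the cohort-level frame (counties, users, truth) from the current RNG
# state; stream synthesis consumes the RNG afterwards, one user at a time in
# user order, so chunked and monolithic generation coincide exactly.
cohort_frame <- function(config) {
  n <- config$n_users
  counties <- generate_counties(config)

  if (n == 0L) {
    empty_users <- tibble::tibble(
      user_id = character(0), zip = character(0), county_fips = character(0),
      state = character(0), median_income = numeric(0),
      first_upload = as.Date(character(0)), last_upload = as.Date(character(0)),
      mobile_app = logical(0), tenure_months = integer(0), region = character(0)
    )
    empty_truth <- tibble::tibble(
      user_id = character(0), baseline_mean = numeric(0), shift = numeric(0),
      county_fips = character(0), median_income = numeric(0),
      tenure_months = integer(0)
    )
    return(list(users = empty_users, counties = counties, truth = empty_truth))
  }

  user_id <- sprintf("u%06d", seq_len(n))
  county_idx <- sample.int(config$n_counties, n, replace = TRUE,
                           prob = counties$user_weight)
  # two zips per county, log-normal zip-level median income
  n_zip <- 2L * config$n_counties
  zip_codes <- sprintf("%05d", 10000L + seq_len(n_zip))
  zip_income <- rlnorm(n_zip, meanlog = log(70000), sdlog = 0.4)
  zip_idx <- 2L * (county_idx - 1L) + sample(c(1L, 2L), n, replace = TRUE)
  income <- zip_income[zip_idx]
  z_inc <- (log(income) - log(70000)) / 0.4 # standardized by design values

  baseline <- config$pop_mean_glucose - config$income_gradient * z_inc +
    rnorm(n, 0, config$between_user_sd)
  baseline <- pmax(baseline, 60) # keep means physiologic
  # Per-user step change, scaled by the user's relative glucose level: a
  # population-wide disturbance moves high-glucose users more in absolute
  # terms. E[shift] stays at pandemic_shift_mean since E[baseline] is the
  # population mean.
  shift <- (baseline / config$pop_mean_glucose) * (
    config$pandemic_shift_mean +
      counties$burden_effect[county_idx] -
      config$income_gradient_shift * z_inc +
      rnorm(n, 0, config$pandemic_shift_sd)
  )

  # tenure mixture: recent adopters through long-term (>= 37 months) users
  mix <- sample.int(3L, n, replace = TRUE, prob = c(0.35, 0.40, 0.25))
  tenure <- integer(n)
  tenure[mix == 1L] <- sample(1:12, sum(mix == 1L), replace = TRUE)
  tenure[mix == 2L] <- sample(13:36, sum(mix == 2L), replace = TRUE)
  tenure[mix == 3L] <- sample(37:60, sum(mix == 3L), replace = TRUE)

  last_upload <- as.Date("2020-06-01") + sample(0:13, n, replace = TRUE)
  # %m-% avoids month-length underflow (e.g. Mar 31 minus 1 month)
  first_upload <- lubridate::`%m-%`(last_upload, months(tenure))
  late <- runif(n) < config$p_late_start
  first_upload[late] <- as.Date("2020-01-01") +
    sample(1:45, sum(late), replace = TRUE)
  tenure <- tenure_months(first_upload, last_upload)
  mobile <- runif(n) < config$p_mobile

  users <- tibble::tibble(
    user_id = user_id,
    zip = zip_codes[zip_idx],
    county_fips = counties$fips[county_idx],
    state = counties$state[county_idx],
    median_income = round(income),
    first_upload = first_upload,
    last_upload = last_upload,
    mobile_app = mobile,
    tenure_months = tenure,
    region = assign_region(counties$state[county_idx])
  )
  truth <- tibble::tibble(
    user_id = user_id,
    baseline_mean = baseline,
    shift = shift,
    county_fips = counties$fips[county_idx],
    median_income = round(income),
    tenure_months = tenure
  )
  list(users = users, counties = counties, truth = truth)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort: %d users, %d counties, %s readings>\n",
    nrow(x$users), nrow(x$counties), format(nrow(x$streams), big.mark = ",")
  ))
  invisible(x)
}

#' Write a synthetic cohort to CSV files
#'
#' Emits the exact schemas the readers consume: `streams.csv`
#' (user_id,timestamp,glucose), `users.csv` (metadata schema),
#' `county_burden.csv` (NYT county schema), and `truth_table.csv`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    streams = file.path(dir, "streams.csv"),
    users = file.path(dir, "users.csv"),
    burden = file.path(dir, "county_burden.csv"),
    truth = file.path(dir, "truth_table.csv")
  )
  write_glucose_csv(cohort$streams, paths[["streams"]])
  readr::write_csv(
    dplyr::select(cohort$users, "user_id", "zip", "county_fips", "state",
                  "median_income", "first_upload", "last_upload", "mobile_app"),
    paths[["users"]]
  )
  readr::write_csv(
    dplyr::select(cohort$counties, "date", "county", "state", "fips",
                  "cases", "deaths"),
    paths[["burden"]]
  )
  readr::write_csv(cohort$truth, paths[["truth"]])
  invisible(paths)
}
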