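#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs: the observation windows, the
#' density rule, metric thresholds, stratification schemes, the county floor
#' and burden snapshot date, the synthetic-generator config (used when no
#' input directory is given), the master seed, and the output directory.
#' When the late-summer window is selected (`use_late_window = TRUE`) the
#' density rule is automatically relaxed, mirroring the study's relaxed
#' analysis of that interval.
#'
#' @param generator A [generator_config()].
#' @param windows Named list with `pre` and `post` [observation_window()]s.
#' @param rule A [density_rule()].
#' @param thresholds A [metric_thresholds()].
#' @param schemes Stratification schemes to run.
#' @param min_users County floor for the burden correlation.
#' @param as_of Burden snapshot date.
#' @param threshold Meaningful TIR change threshold, points.
#' @param use_late_window If `TRUE`, the post window is the late-summer
#'   interval and the density rule is disabled.
#' @param seed Master seed; every stage's randomness derives from it.
#' @param out_dir Output directory for artifacts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            windows = paper_windows()[c("pre", "post")],
                            rule = density_rule(),
                            thresholds = metric_thresholds(),
                            schemes = c("income_bands", "region", "tenure_bands"),
                            min_users = 200L,
                            as_of = as.Date("2020-05-21"),
                            threshold = 5,
                            use_late_window = FALSE,
                            seed = generator$seed,
                            out_dir = tempfile("cgmtrends_run_")) {
  if (use_late_window) {
    windows$post <- paper_windows()$late
    rule <- density_rule(
      rule$min_readings_per_day, rule$min_days_per_week,
      enabled = FALSE, scope = rule$scope
    )
  }
  stopifnot(
    inherits(generator, "generator_config"),
    inherits(windows$pre, "obs_window"), inherits(windows$post, "obs_window"),
    inherits(rule, "density_rule"), inherits(thresholds, "metric_thresholds")
  )
  structure(
    list(
      generator = generator, windows = windows, rule = rule,
      thresholds = thresholds, schemes = schemes,
      min_users = as.integer(min_users), as_of = as.Date(as_of),
      threshold = threshold, seed = as.integer(seed), out_dir = out_dir
    ),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes generate (or ingest) -> filter -> metrics -> compare -> stratify
#' on one configuration, writing every artifact to `config$out_dir`:
#' `inclusion_report.csv`, `metrics_pre.csv`, `metrics_post.csv`,
#' `changes.csv`, `histogram.csv`, `strata.csv`, `county_summaries.csv`
#' (when any county clears the floor), and a machine-readable `summary.json`
#' that lists every written file. Per-stage counts (users in/out, readings)
#' are reported via [message()] so each filter is auditable. Two runs with
#' the same config and seed produce identical summaries.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional pre-built cohort (a [generate_cohort()] result or a
#'   list with `users`, `streams`, and optionally `counties`); when `NULL`, a
#'   synthetic cohort is generated from `config$generator` and `config$seed`.
#' @return List of class `pipeline_result` with `comparison`, `strata`,
#'   `county_summaries`, `correlation`, `included`, `reports`, `summary`
#'   (the JSON-serialized list), and `files`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, ...) message(sprintf("[%s] %s", name, sprintf(...)))

  if (is.null(cohort)) {
    # Generate-and-discard, one user at a time: every inclusion criterion and
    # metric is per-user, so streams never need to be held jointly. The RNG
    # sequence matches generate_cohort() exactly (frame first, then streams
    # in user order), so this path and an in-memory cohort agree.
    set.seed(config$seed)
    frame <- cohort_frame(config$generator)
    users <- frame$users
    counties <- frame$counties
    n <- nrow(users)
    monthly_ok <- logical(n)
    density_pre_ok <- logical(n)
    density_post_ok <- logical(n)
    pre_rows <- vector("list", n)
    post_rows <- vector("list", n)
    n_readings <- 0
    for (i in seq_len(n)) {
      s <- generate_user_stream(
        list(user_id = users$user_id[i],
             baseline_mean = frame$truth$baseline_mean[i],
             shift = frame$truth$shift[i],
             first_upload = users$first_upload[i]),
        config$windows, config$generator
      )
      n_readings <- n_readings + nrow(s)
      has_data <- nrow(s) > 0L
      monthly_ok[i] <- has_data && monthly_presence(s)$present
      density_pre_ok[i] <- if (!config$rule$enabled) TRUE else {
        has_data && passes_density(s, config$windows$pre, config$rule)$passes
      }
      density_post_ok[i] <- if (!config$rule$enabled) TRUE else {
        has_data && passes_density(s, config$windows$post, config$rule)$passes
      }
      included_i <- monthly_ok[i] && density_pre_ok[i] &&
        density_post_ok[i] && users$mobile_app[i] &&
        users$first_upload[i] <= as.Date("2020-01-01")
      if (included_i && has_data) {
        pre_rows[[i]] <- suppressMessages(
          compute_window_metrics(s, config$windows$pre, config$thresholds)
        )
        post_rows[[i]] <- suppressMessages(
          compute_window_metrics(s, config$windows$post, config$thresholds)
        )
      }
    }
    stage("generate", "%d users, %d counties, %d readings",
          n, nrow(counties), n_readings)
    flt <- assemble_inclusion(users, monthly_ok, density_pre_ok,
                              density_post_ok,
                              start_cutoff = as.Date("2020-01-01"))
    stage("filter", "%d of %d users included", nrow(flt$included), n)
    if (nrow(flt$included) < 2L) {
      stop("run_pipeline: fewer than 2 included users after filtering",
           call. = FALSE)
    }
    pre <- dplyr::bind_rows(pre_rows)
    post <- dplyr::bind_rows(post_rows)
  } else {
    stage("ingest", "%d users, %d readings",
          nrow(cohort$users), nrow(cohort$streams))
    users <- cohort$users
    counties <- cohort$counties
    streams <- cohort$streams

    flt <- filter_cohort(users, streams, config$windows$pre,
                         config$windows$post, config$rule)
    stage("filter", "%d of %d users included", nrow(flt$included), nrow(users))
    if (nrow(flt$included) < 2L) {
      stop("run_pipeline: fewer than 2 included users after filtering",
           call. = FALSE)
    }
    kept <- dplyr::filter(streams, .data$user_id %in% flt$included$user_id)

    pre <- compute_window_metrics(kept, config$windows$pre, config$thresholds)
    post <- compute_window_metrics(kept, config$windows$post, config$thresholds)
  }
  stage("metrics", "pre: %d users, post: %d users", nrow(pre), nrow(post))

  comparison <- summarize_comparison(pre, post, config$threshold)
  changes <- tidy(comparison)
  stage("compare", "mean delta TIR %.2f points, p = %.3g",
        comparison$summary$delta_tir_mean, comparison$summary$p_value)

  hist_tbl <- tir_histogram(dplyr::bind_rows(pre, post))

  strata <- dplyr::bind_rows(lapply(config$schemes, function(s) {
    stratify(flt$included, pre, post, scheme = s)
  }))
  stage("stratify", "%d strata across %d scheme(s)",
        nrow(strata), length(config$schemes))

  county_summaries <- NULL
  correlation <- NULL
  if (!is.null(counties)) {
    burden <- dplyr::select(counties, "fips", "deaths")
    county_summaries <- county_improver_fractions(
      changes, flt$included, burden, min_users = config$min_users
    )
    if (nrow(county_summaries) >= 3L &&
        sum(county_summaries$deaths > 0, na.rm = TRUE) >= 3L) {
      correlation <- burden_correlation(county_summaries)
      stage("burden", "r = %.3f over %d counties",
            correlation$r, correlation$n_counties)
    } else {
      stage("burden", "skipped: %d county(ies) cleared the %d-user floor",
            nrow(county_summaries), config$min_users)
    }
  }

  files <- c(
    inclusion_report = file.path(config$out_dir, "inclusion_report.csv"),
    metrics_pre = file.path(config$out_dir, "metrics_pre.csv"),
    metrics_post = file.path(config$out_dir, "metrics_post.csv"),
    changes = file.path(config$out_dir, "changes.csv"),
    histogram = file.path(config$out_dir, "histogram.csv"),
    strata = file.path(config$out_dir, "strata.csv")
  )
  readr::write_csv(dplyr::select(flt$reports, -"failure_reasons"),
                   files[["inclusion_report"]])
  readr::write_csv(pre, files[["metrics_pre"]])
  readr::write_csv(post, files[["metrics_post"]])
  readr::write_csv(changes, files[["changes"]])
  readr::write_csv(hist_tbl, files[["histogram"]])
  readr::write_csv(strata, files[["strata"]])
  if (!is.null(county_summaries) && nrow(county_summaries) > 0L) {
    files[["county_summaries"]] <- file.path(config$out_dir,
                                             "county_summaries.csv")
    readr::write_csv(county_summaries, files[["county_summaries"]])
  }

  summary <- list(
    seed = config$seed,
    windows = list(
      pre = list(label = config$windows$pre$label,
                 start = format(config$windows$pre$start_date),
                 end = format(config$windows$pre$end_date)),
      post = list(label = config$windows$post$label,
                  start = format(config$windows$post$start_date),
                  end = format(config$windows$post$end_date))
    ),
    n_users_input = nrow(users),
    n_users_included = nrow(flt$included),
    comparison = as.list(comparison$summary),
    correlation = if (!is.null(correlation)) as.list(correlation),
    files = as.list(files)
  )
  files[["summary"]] <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(summary, files[["summary"]], auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)

  structure(
    list(
      comparison = comparison, strata = strata,
      county_summaries = county_summaries, correlation = correlation,
      included = flt$included, reports = flt$reports,
      metrics_pre = pre, metrics_post = post,
      summary = summary, files = files
    ),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result: %d/%d users included>\n",
    x$summary$n_users_included, x$summary$n_users_input
  ))
  print(x$comparison)
  if (!is.null(x$correlation)) {
    cat(sprintf("  burden correlation r = %.3f (p = %.3g, %d counties)\n",
                x$correlation$r, x$correlation$p_value,
                x$correlation$n_counties))
  }
  invisible(x)
}
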