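#' Per-county meaningful-improver fractions
#'
#' For each county with at least `min_users` paired users, the fraction of
#' users whose TIR change is a meaningful increase, together with the
#' county's cumulative death count. Counties below the floor are dropped
#' (the study used counties with >= 200 users).
#'
#' @param changes Per-user change tibble with `user_id` and `category`
#'   (from [tidy()] on a [summarize_comparison()] result).
#' @param users User metadata with `user_id` and `county_fips`.
#' @param burden Tibble with `fips` and `deaths` (see
#'   [read_county_burden()]); counties absent from it get `NA` deaths.
#' @param min_users County inclusion floor (default 200).
#' @return Tibble `fips`, `n_users`, `n_meaningful_increase`,
#'   `fraction_meaningful_increase`, `deaths`.
#' @export
county_improver_fractions <- function(changes, users, burden,
                                      min_users = 200L) {
  stopifnot(
    all(c("user_id", "category") %in% names(changes)),
    all(c("user_id", "county_fips") %in% names(users)),
    all(c("fips", "deaths") %in% names(burden))
  )
  changes |>
    dplyr::inner_join(
      dplyr::select(users, "user_id", "county_fips"),
      by = "user_id"
    ) |>
    dplyr::group_by(fips = .data$county_fips) |>
    dplyr::summarise(
      n_users = dplyr::n(),
      n_meaningful_increase = sum(.data$category == "meaningful_increase"),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_users >= .env$min_users) |>
    dplyr::mutate(
      fraction_meaningful_increase = .data$n_meaningful_increase / .data$n_users
    ) |>
    dplyr::left_join(dplyr::select(burden, "fips", "deaths"), by = "fips") |>
    dplyr::arrange(dplyr::desc(.data$n_users))
}

#' County burden vs. TIR-improvement correlation
#'
#' Pearson correlation between the logarithm of county deaths and the
#' fraction of users with meaningful TIR improvement, across counties. The
#' two-sided p-value uses the t transform `t = r * sqrt((n-2)/(1-r^2))` with
#' `n - 2` degrees of freedom. Natural log is used; Pearson r is invariant to
#' the log base and to scaling deaths by a positive constant. Counties with
#' zero (or missing) deaths are excluded rather than offset, with a
#' [message()].
#'
#' @param summaries Tibble from [county_improver_fractions()] (needs
#'   `deaths` and `fraction_meaningful_increase`).
#' @return One-row tibble `r`, `p_value`, `n_counties`.
#' @export
burden_correlation <- function(summaries) {
  stopifnot(all(c("deaths", "fraction_meaningful_increase") %in% names(summaries)))
  usable <- summaries |>
    dplyr::filter(!is.na(.data$deaths), .data$deaths > 0)
  n_dropped <- nrow(summaries) - nrow(usable)
  if (n_dropped > 0L) {
    message(sprintf(
      "burden_correlation: excluded %d county(ies) with zero or missing deaths",
      n_dropped
    ))
  }
  n <- nrow(usable)
  if (n < 3L) {
    stop("burden_correlation: fewer than 3 usable counties", call. = FALSE)
  }
  x <- log(usable$deaths)
  y <- usable$fraction_meaningful_increase
  if (sd(x) == 0 || sd(y) == 0) {
    stop("burden_correlation: zero variance in log-deaths or fractions",
         call. = FALSE)
  }
  # Pearson r from centered cross-products.
  xc <- x - mean(x)
  yc <- y - mean(y)
  r <- sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  tibble::tibble(
    r = r,
    p_value = 2 * pt(-abs(t_stat), n - 2L),
    n_counties = n
  )
}

#' Income and tenure band boundaries
#'
#' Only the top edges are anchored by the study (incomes in excess of
#' $150,000/year; tenures of at least 37 months); interior boundaries are
#' package defaults.
#' @name strata_bands
NULL

default_income_breaks <- c(0, 50000, 100000, 150000, Inf)
default_income_labels <- c("<$50k", "$50k-$100k", "$100k-$150k", ">$150k")
default_tenure_breaks <- c(0, 13, 25, 37, Inf)
default_tenure_labels <- c("<13 mo", "13-24 mo", "25-36 mo", ">=37 mo")

#' Stratified pre/post TIR summaries
#'
#' Partitions the paired cohort into strata — zip-level median household
#' income bands, CDC region, or device-tenure bands — and reports per-stratum
#' pre/post mean TIR with normal-approximation 95% confidence intervals
#' (mean +/- 1.96 SD/sqrt(n)). Every user falls in exactly one stratum; users
#' whose stratum variable is missing go to an `"unknown"` stratum (count
#' reported via [message()]).
#'
#' @param users User metadata (needs `median_income`, `region`, or
#'   `tenure_months` depending on `scheme`).
#' @param pre,post Per-user metric tibbles for the two windows.
#' @param scheme One of `"income_bands"`, `"region"`, `"tenure_bands"`.
#' @param income_breaks,income_labels Income band edges (right-open except
#'   the last) and labels.
#' @param tenure_breaks,tenure_labels Tenure band edges (months) and labels.
#' @return Tibble `scheme`, `stratum`, `n`, `tir_pre_mean`, `tir_pre_lo`,
#'   `tir_pre_hi`, `tir_post_mean`, `tir_post_lo`, `tir_post_hi`,
#'   `delta_tir_mean`.
#' @export
stratify <- function(users, pre, post,
                     scheme = c("income_bands", "region", "tenure_bands"),
                     income_breaks = default_income_breaks,
                     income_labels = default_income_labels,
                     tenure_breaks = default_tenure_breaks,
                     tenure_labels = default_tenure_labels) {
  scheme <- match.arg(scheme)
  paired <- dplyr::inner_join(
    dplyr::select(pre, "user_id", tir_pre = "tir"),
    dplyr::select(post, "user_id", tir_post = "tir"),
    by = "user_id"
  ) |>
    dplyr::inner_join(users, by = "user_id")
  stratum <- switch(
    scheme,
    income_bands = {
      stopifnot("median_income" %in% names(paired))
      as.character(cut(paired$median_income, breaks = income_breaks,
                       labels = income_labels, right = FALSE))
    },
    region = {
      stopifnot("region" %in% names(paired))
      paired$region
    },
    tenure_bands = {
      stopifnot("tenure_months" %in% names(paired))
      as.character(cut(paired$tenure_months, breaks = tenure_breaks,
                       labels = tenure_labels, right = FALSE))
    }
  )
  n_unknown <- sum(is.na(stratum))
  if (n_unknown > 0L) {
    message(sprintf(
      "stratify: %d user(s) with missing %s assigned to 'unknown'",
      n_unknown, scheme
    ))
    stratum[is.na(stratum)] <- "unknown"
  }
  paired$stratum <- stratum
  ci_half <- function(x) 1.96 * sd(x) / sqrt(length(x))
  paired |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(
      n = dplyr::n(),
      tir_pre_mean = mean(.data$tir_pre),
      tir_pre_lo = mean(.data$tir_pre) -
        (if (dplyr::n() >= 2L) ci_half(.data$tir_pre) else 0),
      tir_pre_hi = mean(.data$tir_pre) +
        (if (dplyr::n() >= 2L) ci_half(.data$tir_pre) else 0),
      tir_post_mean = mean(.data$tir_post),
      tir_post_lo = mean(.data$tir_post) -
        (if (dplyr::n() >= 2L) ci_half(.data$tir_post) else 0),
      tir_post_hi = mean(.data$tir_post) +
        (if (dplyr::n() >= 2L) ci_half(.data$tir_post) else 0),
      delta_tir_mean = mean(.data$tir_post - .data$tir_pre),
      .groups = "drop"
    ) |>
    dplyr::mutate(scheme = .env$scheme, .before = 1L)
}
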