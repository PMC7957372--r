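pre_w <- paper_windows()$pre
post_w <- paper_windows()$post

test_that("daily counts zero-fill every calendar day of the window", {
  empty <- tibble::tibble(
    user_id = "u0",
    timestamp = utc("2020-01-07 00:00:00"),
    glucose = 100L
  )[0, ]
  # a user known only from another structure: bind a row outside the window
  s_out <- day_slots("u0", "2019-12-01", 5L)
  dc <- daily_counts(s_out, pre_w)
  expect_equal(nrow(dc), 56L)
  expect_true(all(dc$n == 0L))

  s_full <- multi_day_stream("u1", window_days(pre_w)[1:3], per_day = 288L)
  dc3 <- daily_counts(s_full, observation_window("w3", "2020-01-06", "2020-01-12"))
  expect_equal(dc3$n[1:3], rep(288L, 3))
  expect_equal(dc3$n[4:7], rep(0L, 4))

  # one gap day on a 3-day fixture, counted by hand
  s_gap <- multi_day_stream("u2", as.Date(c("2020-01-06", "2020-01-08")),
                            per_day = 288L)
  dcg <- daily_counts(s_gap, observation_window("wg", "2020-01-06", "2020-01-12"))
  expect_equal(dcg$n[1:3], c(288L, 0L, 288L))
})

test_that("density rule boundary: exactly 200 readings on exactly 4 days/week passes", {
  w2 <- observation_window("toy", "2020-01-06", "2020-01-19")
  days <- window_days(w2)
  # 4 qualifying days in each of the 2 weeks, 0 elsewhere
  s <- multi_day_stream("u1", days[c(1:4, 8:11)], per_day = 200L)
  expect_true(passes_density(s, w2)$passes)
  # 199 readings on one of those days fails that week
  s199 <- multi_day_stream("u2", days[c(1:4, 8:11)],
                           per_day = c(200L, 200L, 200L, 199L, rep(200L, 4)))
  expect_false(passes_density(s199, w2)$passes)
})

test_that("one deficient week fails per-week density even if all others are perfect", {
  days <- window_days(pre_w)
  per_day <- rep(288L, 56L)
  per_day[8:11] <- 0L # week 2 left with only 3 qualifying days
  s <- multi_day_stream("u1", days, per_day = per_day)
  expect_false(passes_density(s, pre_w)$passes)
  # but the window-total reading of the rule accepts it (52 >= 32 days)
  expect_true(passes_density(s, pre_w, density_rule(scope = "per_window"))$passes)
  # and a disabled rule always passes
  expect_true(passes_density(s, pre_w, density_rule(enabled = FALSE))$passes)
})

test_that("monthly presence requires at least one reading in every month", {
  firsts <- seq(as.Date("2020-01-01"), as.Date("2020-06-01"), by = "month")
  s_all <- multi_day_stream("u1", firsts, per_day = 1L)
  expect_true(monthly_presence(s_all)$present)
  s_no_feb <- multi_day_stream("u2", firsts[-2], per_day = 1L)
  expect_false(monthly_presence(s_no_feb)$present)
  s_june_only <- day_slots("u3", "2020-06-30", 1L)
  expect_false(monthly_presence(s_june_only)$present)
})

test_that("inclusion criteria produce one report per user with exact reasons", {
  users <- tibble::tibble(
    user_id = c("ok", "late", "receiver", "gap_month", "sparse_pre"),
    first_upload = as.Date(c("2019-06-01", "2020-01-02", "2019-06-01",
                             "2019-06-01", "2019-06-01")),
    mobile_app = c(TRUE, TRUE, FALSE, TRUE, TRUE)
  )
  ok <- compliant_stream("ok")
  late <- compliant_stream("late")
  receiver <- compliant_stream("receiver")
  gap_month <- dplyr::filter(
    compliant_stream("gap_month"),
    format(timestamp, "%Y-%m", tz = "UTC") != "2020-03"
  )
  # drop enough prepandemic days to break week 1 (3 qualifying days left)
  sparse_pre <- dplyr::filter(
    compliant_stream("sparse_pre"),
    !(as.Date(timestamp) %in% window_days(pre_w)[1:4])
  )
  streams <- dplyr::bind_rows(ok, late, receiver, gap_month, sparse_pre)
  flt <- filter_cohort(users, streams, pre_w, post_w)

  expect_equal(nrow(flt$reports), nrow(users))
  expect_setequal(flt$included$user_id, "ok")
  rep_of <- function(id) flt$reports$failure_reasons[[match(id, flt$reports$user_id)]]
  expect_length(rep_of("ok"), 0L)
  expect_equal(rep_of("late"), "late_start")
  expect_equal(rep_of("receiver"), "not_mobile")
  expect_equal(rep_of("gap_month"), "missing_month")
  expect_equal(rep_of("sparse_pre"), "density_pre")
  # passed <=> empty reasons; included/excluded partition the cohort
  expect_equal(flt$reports$passed, lengths(flt$reports$failure_reasons) == 0L)
  expect_equal(nrow(flt$included) + sum(!flt$reports$passed), nrow(users))
})

test_that("first_upload exactly on the cutoff date is included", {
  users <- tibble::tibble(
    user_id = "edge", first_upload = as.Date("2020-01-01"), mobile_app = TRUE
  )
  flt <- filter_cohort(users, compliant_stream("edge"), pre_w, post_w)
  expect_true(flt$reports$passed)
})

test_that("a user without any stream fails the stream-based criteria", {
  users <- tibble::tibble(
    user_id = c("present", "ghost"),
    first_upload = as.Date("2019-06-01"), mobile_app = TRUE
  )
  flt <- filter_cohort(users, compliant_stream("present"), pre_w, post_w)
  expect_setequal(
    flt$reports$failure_reasons[[2]],
    c("missing_month", "density_pre", "density_post")
  )
})

test_that("weakening the density rule never removes an included user", {
  set.seed(202)
  days <- window_days(pre_w)
  post_days <- window_days(post_w)
  streams <- dplyr::bind_rows(lapply(1:12, function(i) {
    id <- sprintf("r%02d", i)
    dplyr::bind_rows(
      multi_day_stream(id, days, per_day = sample(0:288, 56, replace = TRUE)),
      multi_day_stream(id, post_days, per_day = sample(0:288, 56, replace = TRUE)),
      day_slots(id, "2020-03-15", 1L)
    )
  }))
  users <- tibble::tibble(
    user_id = sprintf("r%02d", 1:12),
    first_upload = as.Date("2019-06-01"), mobile_app = TRUE
  )
  strict <- filter_cohort(users, streams, pre_w, post_w,
                          density_rule(200L, 4L))
  lower_days <- filter_cohort(users, streams, pre_w, post_w,
                              density_rule(200L, 2L))
  lower_readings <- filter_cohort(users, streams, pre_w, post_w,
                                  density_rule(100L, 4L))
  disabled <- filter_cohort(users, streams, pre_w, post_w,
                            density_rule(enabled = FALSE))
  expect_true(all(strict$included$user_id %in% lower_days$included$user_id))
  expect_true(all(strict$included$user_id %in% lower_readings$included$user_id))
  expect_true(all(strict$included$user_id %in% disabled$included$user_id))
  # disabled rule reduces inclusion to the three non-density criteria
  expect_equal(nrow(disabled$included), 12L)
})
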