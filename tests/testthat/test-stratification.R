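toy_changes <- function(counts) {
  # counts: named list fips -> c(increase, decrease, intermediate)
  rows <- lapply(names(counts), function(f) {
    k <- counts[[f]]
    n <- sum(k)
    tibble::tibble(
      user_id = sprintf("%s_%03d", f, seq_len(n)),
      category = factor(
        rep(c("meaningful_increase", "meaningful_decrease", "intermediate"), k),
        levels = c("meaningful_decrease", "intermediate", "meaningful_increase")
      ),
      fips = f
    )
  })
  dplyr::bind_rows(rows)
}

test_that("county improver fractions enumerate categories and honour the floor", {
  ch <- toy_changes(list(A = c(3, 1, 1), B = c(0, 0, 4), C = c(4, 0, 0)))
  users <- tibble::tibble(user_id = ch$user_id, county_fips = ch$fips)
  burden <- tibble::tibble(fips = c("A", "B", "C"), deaths = c(10, 20, 30))
  cs <- county_improver_fractions(dplyr::select(ch, user_id, category),
                                  users, burden, min_users = 1)
  cs <- cs[order(cs$fips), ]
  expect_equal(cs$fraction_meaningful_increase, c(3 / 5, 0, 1))
  expect_equal(cs$deaths, c(10, 20, 30))

  # 199 users misses a 200-user floor; 200 exactly clears it
  big <- toy_changes(list(D = c(100, 50, 49), E = c(100, 50, 50)))
  users_big <- tibble::tibble(user_id = big$user_id, county_fips = big$fips)
  burden_big <- tibble::tibble(fips = c("D", "E"), deaths = c(5, 6))
  cs_big <- county_improver_fractions(dplyr::select(big, user_id, category),
                                      users_big, burden_big, min_users = 200)
  expect_equal(cs_big$fips, "E")
  expect_equal(cs_big$n_users, 200L)

  # raising the floor never adds counties
  for (floor_k in c(1, 3, 5)) {
    lo <- county_improver_fractions(dplyr::select(ch, user_id, category),
                                    users, burden, min_users = floor_k)
    hi <- county_improver_fractions(dplyr::select(ch, user_id, category),
                                    users, burden, min_users = floor_k + 1)
    expect_lte(nrow(hi), nrow(lo))
  }
})

test_that("burden correlation is exact on collinear data and matches oracles", {
  collinear <- tibble::tibble(
    fips = c("A", "B", "C"),
    deaths = c(10, 100, 1000),
    fraction_meaningful_increase = c(0.2, 0.3, 0.4)
  )
  expect_equal(burden_correlation(collinear)$r, 1, tolerance = 1e-12)

  # invariant to scaling deaths by a positive constant (log-base invariance)
  scaled <- dplyr::mutate(collinear, deaths = deaths * 7)
  expect_equal(burden_correlation(scaled)$r, burden_correlation(collinear)$r,
               tolerance = 1e-12)

  four <- tibble::tibble(
    fips = c("A", "B", "C", "D"),
    deaths = c(12, 45, 230, 890),
    fraction_meaningful_increase = c(0.21, 0.34, 0.30, 0.42)
  )
  ours <- burden_correlation(four)
  expect_equal(ours$r, oracle_pearson(log(four$deaths),
                                      four$fraction_meaningful_increase),
               tolerance = 1e-12)
  ref <- stats::cor.test(log(four$deaths), four$fraction_meaningful_increase)
  expect_equal(ours$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)

  set.seed(606)
  for (i in 1:100) {
    n <- sample(4:40, 1)
    tbl <- tibble::tibble(
      fips = as.character(seq_len(n)),
      deaths = round(rlnorm(n, 3, 1.5)) + 1,
      fraction_meaningful_increase = runif(n)
    )
    ours <- burden_correlation(tbl)
    ref <- stats::cor.test(log(tbl$deaths), tbl$fraction_meaningful_increase)
    expect_equal(ours$r, unname(ref$estimate), tolerance = 1e-9)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("burden correlation rejects degenerate inputs and drops zero-death counties", {
  zero <- tibble::tibble(
    fips = c("A", "B", "C", "Z"),
    deaths = c(10, 100, 1000, 0),
    fraction_meaningful_increase = c(0.2, 0.3, 0.4, 0.9)
  )
  expect_message(r <- burden_correlation(zero), "zero or missing")
  expect_equal(r$n_counties, 3L)
  expect_error(suppressMessages(burden_correlation(zero[c(1, 4), ])),
               "fewer than 3")
  const <- tibble::tibble(
    fips = c("A", "B", "C"), deaths = c(10, 10, 10),
    fraction_meaningful_increase = c(0.2, 0.3, 0.4)
  )
  expect_error(burden_correlation(const), "zero variance")
})

test_that("strata partition the cohort under every scheme", {
  set.seed(707)
  n <- 80
  users <- tibble::tibble(
    user_id = sprintf("u%03d", 1:n),
    median_income = round(rlnorm(n, log(8e4), 0.5)),
    region = sample(c("Colorado", "Washington", "unassigned"), n, TRUE),
    tenure_months = sample(1:60, n, TRUE)
  )
  pre <- dplyr::bind_rows(lapply(users$user_id, function(i) {
    metric_row(i, runif(1, 20, 90))
  }))
  post <- dplyr::bind_rows(lapply(users$user_id, function(i) {
    metric_row(i, runif(1, 20, 90))
  }))
  for (scheme in c("income_bands", "region", "tenure_bands")) {
    st <- stratify(users, pre, post, scheme = scheme)
    expect_equal(sum(st$n), n)
    # normal-approximation CI brackets the mean and has positive width for n>=2
    expect_true(all(st$tir_pre_lo <= st$tir_pre_mean))
    expect_true(all(st$tir_pre_hi >= st$tir_pre_mean))
  }
  # single income value populates a single band
  users1 <- dplyr::mutate(users, median_income = 60000)
  st1 <- stratify(users1, pre, post, scheme = "income_bands")
  expect_equal(st1$stratum, "$50k-$100k")
  # missing stratum variable goes to 'unknown'
  users_na <- users
  users_na$median_income[1] <- NA
  expect_message(
    st_na <- stratify(users_na, pre, post, scheme = "income_bands"),
    "unknown"
  )
  expect_true("unknown" %in% st_na$stratum)
  expect_equal(sum(st_na$n), n)
})

test_that("an income gradient in the generator yields income-ordered baseline TIR", {
  cfg <- generator_config(
    n_users = 250, n_counties = 4, seed = 41,
    income_gradient = 25, income_gradient_shift = 0,
    pandemic_shift_sd = 0, burden_coupling = 0, p_late_start = 0, p_mobile = 1,
    daily_dropout_prob = 0, within_day_missing_frac = 0.5
  )
  w <- observation_window("prepandemic", "2020-01-06", "2020-01-12")
  coh <- generate_cohort(cfg, windows = list(w))
  pre <- compute_window_metrics(coh$streams, w)
  st <- stratify(coh$users, pre, pre, scheme = "income_bands")
  st <- st[match(c("<$50k", "$50k-$100k", "$100k-$150k", ">$150k"), st$stratum), ]
  st <- st[!is.na(st$n) & st$n >= 5, ]
  # top populated band clearly above bottom populated band
  expect_gt(dplyr::last(st$tir_pre_mean), dplyr::first(st$tir_pre_mean))
})

test_that("burden coupling induces a positive county correlation, none without it", {
  run_r <- function(coupling, seed) {
    cfg <- generator_config(
      n_users = 240, n_counties = 8, seed = seed,
      burden_coupling = coupling, pandemic_shift_mean = 0,
      pandemic_shift_sd = 8, income_gradient = 0, income_gradient_shift = 0,
      p_late_start = 0, p_mobile = 1,
      daily_dropout_prob = 0, within_day_missing_frac = 0.6
    )
    toy <- list(
      pre = observation_window("prepandemic", "2020-01-06", "2020-01-12"),
      post = observation_window("intrapandemic", "2020-04-20", "2020-04-26")
    )
    coh <- generate_cohort(cfg, windows = toy)
    pre <- compute_window_metrics(coh$streams, toy$pre)
    post <- compute_window_metrics(coh$streams, toy$post)
    ch <- tidy(summarize_comparison(pre, post, threshold = 2))
    cs <- county_improver_fractions(ch, coh$users,
                                    dplyr::select(coh$counties, fips, deaths),
                                    min_users = 3)
    suppressMessages(burden_correlation(cs)$r)
  }
  seeds <- 101:112
  with_coupling <- vapply(seeds, function(s) run_r(12, s), numeric(1))
  without <- vapply(seeds, function(s) run_r(0, s), numeric(1))
  expect_gte(mean(with_coupling > 0), 0.9)
  expect_gt(mean(with_coupling), mean(without))
  # no coupling: correlation centered near zero
  expect_lt(abs(mean(without)), 2.5 * sd(without) / sqrt(length(seeds)) + 0.25)
})
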