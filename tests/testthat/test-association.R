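make_small_study <- function(seed = 23, n_drivers = 6, n_days = 5, ...) {
  spec <- cohort_spec(n_drivers = n_drivers, n_days = n_days, seed = seed, ...)
  co <- generate_cohort(spec)
  hrv <- summarize_hrv(co$recordings, co$drivers, norms = spec$norms)
  daily <- daily_risk_table(co$events, co$cohort)
  list(co = co, hrv = hrv, daily = daily,
       records = build_records(hrv, daily, co$cohort))
}

test_that("records join the three streams with previous-day lags", {
  st <- make_small_study()
  expect_equal(nrow(st$records), nrow(st$co$cohort))
  # lagged post-shift score matches the previous calendar day's value
  r2 <- dplyr::filter(st$records, date == min(date) + 1)
  prev <- dplyr::filter(st$hrv, condition == "post_shift", date == min(date))
  j <- dplyr::inner_join(r2, dplyr::select(prev, driver_id, lf_score),
                         by = "driver_id")
  expect_equal(j$lf_score_post_prev, j$lf_score)
  # first study day has no previous day
  d1 <- dplyr::filter(st$records, date == min(date))
  expect_true(all(is.na(d1$lf_score_post_prev)))
})

test_that("flat-VAS drivers and never-warned drivers are flagged for exclusion", {
  st <- make_small_study()
  vas2 <- st$co$cohort
  vas2$vas_pre[vas2$driver_id == "D01"] <- 50
  vas2$vas_post[vas2$driver_id == "D01"] <- 50
  rec <- build_records(st$hrv, st$daily, vas2)
  expect_true(all(rec$excluded_vas[rec$driver_id == "D01"]))
  expect_false(any(rec$analysis_ready[rec$driver_id == "D01"]))
  expect_false(any(rec$excluded_vas[rec$driver_id != "D01"]))

  daily2 <- st$daily
  daily2$n_events[daily2$driver_id == "D02"] <- 0L
  daily2$R[daily2$driver_id == "D02"] <- 0L
  rec2 <- build_records(st$hrv, daily2, st$co$cohort)
  expect_true(all(rec2$excluded_no_warnings[rec2$driver_id == "D02"]))
  expect_false(any(rec2$analysis_ready[rec2$driver_id == "D02"]))
})

test_that("disjoint dates give an empty join and duplicate keys an error", {
  st <- make_small_study()
  shifted <- dplyr::mutate(st$co$cohort, date = date + 1000)
  rec <- build_records(st$hrv, st$daily, shifted)
  expect_equal(nrow(rec), 0)
  expect_error(build_records(dplyr::bind_rows(st$hrv, st$hrv[1, ]),
                             st$daily, st$co$cohort), "duplicate")
})

test_that("correlation matches its closed-form cases and is symmetric", {
  x <- 1:20
  expect_equal(correlate(x, 2 * x + 1)$r, 1.0)
  expect_equal(correlate(x, -3 * x + 7)$r, -1.0)
  y <- withr::with_seed(1, rnorm(2000))
  r_null <- correlate(seq_along(y), y)
  expect_lt(abs(r_null$r), 0.05)
  a <- withr::with_seed(2, rnorm(30)); b <- withr::with_seed(3, rnorm(30))
  expect_equal(correlate(a, b)$r, correlate(b, a)$r)
  # invariance under positive affine transforms
  expect_equal(correlate(10 * a - 4, b)$r, correlate(a, b)$r)
  expect_equal(correlate(a, b)$p, cor.test(a, b)$p.value)
  expect_error(correlate(1:2, 1:2), "at least 3")
  expect_error(correlate(rep(1, 10), 1:10), "zero variance")
})

test_that("median split assigns ties low and reports Welch statistics", {
  rec <- tibble::tibble(r_1hr = c(1, 2, 3, 4), v = c(10, 11, 20, 21))
  gc <- median_split_test(rec, "v")
  expect_equal(gc$threshold, 2.5)
  expect_equal(gc$n_high, 2)
  expect_equal(gc$n_low, 2)
  expect_equal(gc$mean_high, 20.5)
  # ties at the median go to the low group
  rec2 <- tibble::tibble(r_1hr = c(1, 2, 2, 4, 5), v = 1:5)
  gc2 <- median_split_test(rec2, "v")
  expect_equal(gc2$n_low, 3)
  expect_error(median_split_test(tibble::tibble(r_1hr = rep(2, 6), v = 1:6), "v"),
               "degenerate")
})

test_that("Welch's t equals Student's t for equal sizes and variances", {
  a <- c(4.1, 5.2, 6.3, 4.8, 5.5, 6.0)
  b <- a + 1
  rec <- tibble::tibble(r_1hr = rep(c(1, 9), each = 6), v = c(a, b))
  gc <- median_split_test(rec, "v")
  tt <- t.test(b, a, var.equal = TRUE)
  expect_equal(gc$t, unname(tt$statistic), tolerance = 1e-12)
})

test_that("median split detects a one-SD shift with the power the t-test promises", {
  n <- 30
  power <- stats::power.t.test(n = n, delta = 1, sd = 1, sig.level = 0.05)$power
  rej <- vapply(1:200, function(s) {
    v <- withr::with_seed(s, c(rnorm(n, 0), rnorm(n, 1)))
    rec <- tibble::tibble(r_1hr = rep(c(0, 9), each = n), v = v)
    median_split_test(rec, "v")$p < 0.05
  }, logical(1))
  expect_equal(mean(rej), power, tolerance = 0.10)
})

test_that("association battery runs the documented tests and counts them", {
  st <- make_small_study(seed = 31, n_drivers = 8, n_days = 6)
  res <- run_association(st$records)
  expect_named(res$correlations,
               c("vas_pre", "vas_post", "lf_score_pre", "lf_hf_pre",
                 "lf_score_post_prev", "lf_hf_post_prev"))
  expect_s3_class(res$correlations$vas_pre, "correlation_result")
  expect_true(res$n_tests >= 6)
  expect_true(!is.null(res$group_comparison))
})

test_that("fatigue-risk coupling strengthens with the generator's slope", {
  mean_r <- function(beta) {
    mean(vapply(1:4, function(s) {
      st <- make_small_study(seed = 100 + s, n_drivers = 10, n_days = 6,
                             beta_risk = beta)
      use <- dplyr::filter(st$records, analysis_ready,
                           is.finite(lf_score_post_prev), is.finite(r_1hr))
      correlate(use$lf_score_post_prev, use$r_1hr)$r
    }, numeric(1)))
  }
  rs <- c(mean_r(0), mean_r(0.15), mean_r(0.4))
  expect_true(all(diff(rs) > 0))
  expect_gt(rs[3], 0.3)
})
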