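test_that("feature extraction matches direct arithmetic", {
  f <- extract_features(rep(50, 10))
  expect_equal(unlist(f), c(duration = 10, max_speed = 50, min_speed = 50,
                            avg_speed = 50, speed_deviation = 0,
                            max_decel_per_s = 0))

  expect_equal(extract_features(c(60, 55, 49))$max_decel_per_s, 6)

  s <- c(87, 80, 70, 61, 55, 50, 47, 45, 44, 40, 37, 35, 34)  # 13-s slowdown
  f2 <- extract_features(s)
  expect_equal(f2$duration, 13)
  expect_equal(f2$max_speed, max(s))
  expect_equal(f2$min_speed, min(s))
  expect_equal(f2$avg_speed, mean(s))
  expect_equal(f2$speed_deviation, sd(s))
  expect_equal(f2$max_decel_per_s, max(-diff(s)))

  # accelerating profile: deceleration floored at zero
  expect_equal(extract_features(c(30, 35, 41))$max_decel_per_s, 0)

  expect_error(extract_features(55), "at least 2")
  expect_error(extract_features(rep(50, 10), duration_s = 20), "1-Hz")
})

test_that("vectorised event features agree with the scalar extractor", {
  ev <- generate_events(50, 0.5, 0, seed = 13)
  batch <- event_features(ev)
  for (i in c(1, 17, 50)) {
    single <- extract_features(ev$speeds[[i]], ev$duration_s[i])
    expect_equal(unlist(batch[i, names(single)]), unlist(single))
  }
})

test_that("reference rules classify the printed example situations", {
  # sustained highway warning: long, moderate deviation, at speed
  expect_equal(rule_classify(feat_row(80, 45, 6.0)), 1L)
  # congested low-speed warning: deviation irrelevant
  expect_equal(rule_classify(feat_row(50, 35, 2.0)), 1L)
  expect_equal(rule_classify(feat_row(50, 35, 9.0)), 1L)
  # the worked short-duration example row fails both duration conditions
  expect_equal(rule_classify(feat_row(13, 87, 6, min_speed = 34, avg_speed = 56,
                                      max_decel_per_s = 3)), 0L)
})

test_that("rule thresholds have the documented comparator orientation", {
  eps <- 1e-6
  grid <- expand.grid(
    duration = c(42.5 - eps, 42.5 + eps, 79.0 - eps, 79.0 + eps),
    speed_deviation = c(5.8 - eps, 5.8 + eps, 6.5 - eps, 6.5 + eps),
    max_speed = c(39 - eps, 39 + eps)
  )
  got <- rule_classify(feat_row(grid$duration, grid$max_speed, grid$speed_deviation))
  want <- oracle_rules(grid$duration, grid$speed_deviation, grid$max_speed)
  expect_identical(got, want)
  # spot checks on each comparator
  expect_equal(rule_classify(feat_row(79.0, 45, 6.0)), 0L)       # "greater than" strict
  expect_equal(rule_classify(feat_row(79.0 + eps, 45, 6.5)), 1L) # 6.5 inclusive
  expect_equal(rule_classify(feat_row(79.0 + eps, 45, 5.8)), 0L) # 5.8 exclusive
  expect_equal(rule_classify(feat_row(50, 39, 2)), 0L)           # "less than" strict
})

test_that("CART trained on zero-noise events reproduces the rules on fresh data", {
  train <- generate_events(285, 40 / 285, label_noise = 0, seed = 11)
  test <- generate_events(1000, 0.4, label_noise = 0, seed = 1011)
  model <- train_tree(event_features(train), train$label, seed = 11)
  pred <- predict(model, event_features(test))
  expect_gte(mean(pred == rule_classify(event_features(test))), 0.99)
  # deterministic given seed
  model2 <- train_tree(event_features(train), train$label, seed = 11)
  expect_identical(predict(model2, event_features(test)), pred)
})

test_that("training on negated labels learns the negated rules", {
  train <- generate_events(285, 40 / 285, label_noise = 0, seed = 12)
  test <- generate_events(500, 0.4, label_noise = 0, seed = 1012)
  model <- train_tree(event_features(train), 1L - train$label, seed = 12)
  pred <- predict(model, event_features(test))
  expect_gte(mean(pred == 1L - rule_classify(event_features(test))), 0.99)
})

test_that("restricting the depth grid cannot improve cross-validated accuracy", {
  train <- generate_events(200, 0.4, label_noise = 0.05, seed = 14)
  f <- event_features(train)
  shallow <- train_tree(f, train$label, depth_grid = 1, seed = 14)
  full <- train_tree(f, train$label, depth_grid = 1:6, seed = 14)
  expect_lte(max(shallow$cv$cv_accuracy), max(full$cv$cv_accuracy))
})

test_that("train_tree guards its preconditions", {
  ev <- generate_events(20, 0, 0, seed = 1)  # single class
  f <- event_features(ev)
  expect_error(train_tree(f, ev$label), "both classes")
  ev2 <- generate_events(4, 0.5, 0, seed = 2)
  expect_error(train_tree(event_features(ev2), c(0, 1, 0, 1), folds = 5), "folds")
})

test_that("confusion-matrix evaluation returns the published-style summary", {
  # predicted x actual: TP = 4, FN = 2, FP = 2, TN = 17
  m <- matrix(c(4, 2, 2, 17), nrow = 2, byrow = TRUE)
  s <- confusion_summary(m)
  expect_equal(s$accuracy_pct, 84.0)
  expect_equal(s$baseline_pct, 24.0)
  expect_equal(s$n, 25)

  perfect <- evaluate_predictions(c(1, 1, 0, 0, 0), c(1, 1, 0, 0, 0))
  expect_equal(perfect$accuracy_pct, 100)
  expect_equal(sum(perfect$confusion) - sum(diag(perfect$confusion)), 0)

  expect_error(evaluate_predictions(integer(0), integer(0)), "empty")
  expect_error(evaluate_predictions(c(1, 2), c(0, 1)), "binary")
})

test_that("accuracy identity and baseline independence hold across random label sets", {
  for (seed in 1:5) {
    z <- withr::with_seed(seed, list(p = rbinom(60, 1, 0.4), a = rbinom(60, 1, 0.3)))
    ev <- evaluate_predictions(z$p, z$a)
    fp <- ev$confusion[1, 2]; fn <- ev$confusion[2, 1]
    expect_equal(ev$accuracy_pct, 100 * (1 - (fp + fn) / ev$n))
    expect_equal(ev$baseline_pct, 100 * mean(z$a))  # ignores predictions
  }
})

test_that("daily index divides risk count by hours and excludes short shifts", {
  d <- daily_index(rep(1, 8), 4)
  expect_equal(d$r_1hr, 2.0)
  expect_true(d$included)
  expect_equal(d$R, 8)

  short <- daily_index(rep(1, 5), 2.5)
  expect_false(short$included)
  expect_true(is.na(short$r_1hr))

  none <- daily_index(integer(0), 10)
  expect_equal(none$R, 0)
  expect_equal(none$r_1hr, 0)
  expect_error(daily_index(c(1, 0), -2), "wt_hours")
})

test_that("r_1hr is exact and invariant to event order", {
  labels <- c(1, 0, 1, 1, 0, 1)
  a <- daily_index(labels, 3.7)
  b <- daily_index(rev(labels), 3.7)
  expect_identical(a, b)
  expect_equal(a$r_1hr * a$wt_hours, a$R)
})

test_that("daily risk table matches per-day indexing and keeps empty days", {
  co <- generate_cohort(cohort_spec(n_drivers = 3, n_days = 3, seed = 19))
  daily <- daily_risk_table(co$events, co$cohort)
  expect_equal(nrow(daily), nrow(co$cohort))
  one <- dplyr::filter(co$events, driver_id == daily$driver_id[1],
                       date == daily$date[1])
  expect_equal(daily$R[1], sum(rule_classify(event_features(one)) == 1))
  expect_identical(daily$included, daily$wt_hours >= 3)
})
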