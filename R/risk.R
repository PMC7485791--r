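#' Extract behavioural features from a warning event
#'
#' A warning event carries the vehicle speed sampled at 1 Hz while the
#' inter-vehicle-distance alarm sounds. Six features summarise the
#' vehicle behaviour over the warning: duration (s), maximum / minimum /
#' average speed (km/h), the standard deviation of speed, and the
#' maximum 1-s deceleration (largest drop between consecutive samples,
#' floored at 0).
#'
#' @param speed_samples numeric vector of speeds (km/h) at 1 Hz; at
#'   least 2 samples.
#' @param duration_s event duration (s); defaults to the number of
#'   samples (1-Hz cadence).
#' @return One-row tibble: `duration`, `max_speed`, `min_speed`,
#'   `avg_speed`, `speed_deviation`, `max_decel_per_s`.
#' @examples
#' extract_features(c(60, 55, 49)) # max_decel_per_s = 6
#' @export
extract_features <- function(speed_samples, duration_s = length(speed_samples)) {
  if (length(speed_samples) < 2) stop_("need at least 2 speed samples to extract features")
  if (abs(length(speed_samples) - duration_s) > 1)
    stop_("sample count (%d) inconsistent with a 1-Hz cadence over %g s",
          length(speed_samples), duration_s)
  drops <- -diff(speed_samples)
  tibble(
    duration = duration_s,
    max_speed = max(speed_samples),
    min_speed = min(speed_samples),
    avg_speed = mean(speed_samples),
    speed_deviation = sd(speed_samples),
    max_decel_per_s = max(c(drops, 0))
  )
}

#' Feature table for a set of warning events
#'
#' @param events tibble in nested form: one row per event with at least
#'   `event_id` and a list-column `speeds`; optional `duration_s`.
#' @return `events`' key columns joined with one feature row per event.
#' @export
event_features <- function(events) {
  stopifnot("speeds" %in% names(events))
  dur <- if ("duration_s" %in% names(events)) events$duration_s else lengths(events$speeds)
  bad <- lengths(events$speeds) < 2
  if (any(bad)) stop_("event(s) with fewer than 2 speed samples: %s",
                      paste(head(which(bad), 3), collapse = ", "))
  if (any(abs(lengths(events$speeds) - dur) > 1))
    stop_("speed sample counts inconsistent with a 1-Hz cadence")
  # same definitions as extract_features(), vectorised over the list-column
  m <- vapply(events$speeds, function(s) {
    c(max(s), min(s), mean(s), sd(s), max(c(-diff(s), 0)))
  }, numeric(5))
  dplyr::bind_cols(
    select(events, -dplyr::any_of("speeds")),
    tibble(duration = as.numeric(dur), max_speed = m[1, ], min_speed = m[2, ],
           avg_speed = m[3, ], speed_deviation = m[4, ], max_decel_per_s = m[5, ])
  )
}

#' Reference decision rules for collision-risk classification
#'
#' The reference rule set classifies a warning event as a rear-end
#' collision risk (1) when either of two situations holds:
#'
#' * **Sustained highway warning**: duration > 79.0 s, speed deviation
#'   in (5.8, 6.5] km/h, and maximum speed > 39 km/h — intermittent
#'   acceleration/deceleration at speed with the distance warning
#'   sounding for a long period.
#' * **Congested low-speed warning**: duration > 42.5 s and maximum
#'   speed < 39 km/h — the warning sounding intermittently in congestion
#'   at low speed.
#'
#' Comparator orientation follows the CART convention (a left branch
#' takes `<=` the threshold): "greater than" is strict and "less than or
#' equal" inclusive, so the deviation interval is open at 5.8 and closed
#' at 6.5.
#'
#' @param features tibble of event features (columns as produced by
#'   [extract_features()]); vectorised over rows.
#' @return Integer vector of 0/1 labels.
#' @examples
#' rule_classify(tibble::tibble(duration = 50, max_speed = 35,
#'   min_speed = 20, avg_speed = 28, speed_deviation = 3, max_decel_per_s = 2))
#' @export
rule_classify <- function(features) {
  need <- c("duration", "max_speed", "speed_deviation")
  miss <- setdiff(need, names(features))
  if (length(miss) > 0) stop_("features missing column(s): %s", paste(miss, collapse = ", "))
  rule1 <- features$duration > 79.0 &
    features$speed_deviation > 5.8 & features$speed_deviation <= 6.5 &
    features$max_speed > 39
  rule2 <- features$duration > 42.5 & features$max_speed < 39
  as.integer(rule1 | rule2)
}

#' Train a CART collision-risk classifier
#'
#' Fits a Gini-impurity CART to labelled event features, choosing
#' hyperparameters (tree depth, minimum leaf size) by grid search over
#' mean accuracy in seeded, class-stratified 5-fold cross-validation,
#' then refits the winning configuration on all data. Ties in CV
#' accuracy go to the shallower tree, then the larger leaf.
#'
#' @param features tibble of event features.
#' @param labels integer/numeric 0/1 vector, both classes present.
#' @param folds number of CV folds.
#' @param depth_grid,minleaf_grid hyperparameter grids.
#' @param seed integer seed controlling fold assignment.
#' @return A `risk_model`: the fitted `rpart` tree plus training
#'   metadata (grid results, chosen hyperparameters, folds, seed).
#' @export
train_tree <- function(features, labels, folds = 5,
                       depth_grid = 1:6, minleaf_grid = c(1, 5, 10),
                       seed = 1) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop_("need both classes present to train a classifier")
  if (length(labels) != nrow(features)) stop_("features and labels lengths differ")
  if (length(labels) < folds) stop_("fewer events (%d) than folds (%d)", length(labels), folds)
  dat <- as.data.frame(features[feature_cols()])
  dat$.label <- factor(labels, levels = c(0, 1))

  fold_id <- with_seed_(seed, stratified_folds(labels, folds))
  grid <- expand.grid(maxdepth = depth_grid, minbucket = minleaf_grid)
  grid$cv_accuracy <- NA_real_
  for (g in seq_len(nrow(grid))) {
    acc <- numeric(folds)
    for (k in seq_len(folds)) {
      tr <- fold_id != k
      fit <- fit_rpart(dat[tr, ], grid$maxdepth[g], grid$minbucket[g])
      pred <- predict(fit, dat[!tr, ], type = "class")
      acc[k] <- mean(pred == dat$.label[!tr])
    }
    grid$cv_accuracy[g] <- mean(acc)
  }
  best <- grid[order(-grid$cv_accuracy, grid$maxdepth, -grid$minbucket), ][1, ]
  tree <- fit_rpart(dat, best$maxdepth, best$minbucket)
  structure(list(
    tree = tree,
    chosen = list(maxdepth = best$maxdepth, minbucket = best$minbucket),
    cv = as_tibble(grid), folds = folds, fold_id = fold_id, seed = seed
  ), class = "risk_model")
}

feature_cols <- function() {
  c("duration", "max_speed", "min_speed", "avg_speed",
    "speed_deviation", "max_decel_per_s")
}

fit_rpart <- function(dat, maxdepth, minbucket) {
  rpart::rpart(.label ~ ., data = dat, method = "class",
               parms = list(split = "gini"),
               control = rpart::rpart.control(
                 maxdepth = maxdepth, minbucket = minbucket,
                 minsplit = max(2, 2 * minbucket), cp = 0, xval = 0,
                 maxcompete = 0, maxsurrogate = 0, usesurrogate = 0))
}

# class-stratified fold labels 1..folds (assumes ambient RNG already seeded)
stratified_folds <- function(labels, folds) {
  fold_id <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold_id
}

#' Predict collision-risk labels
#'
#' @param object a `risk_model` from [train_tree()].
#' @param features tibble of event features.
#' @param ... unused.
#' @return Integer 0/1 vector; deterministic given the features.
#' @export
predict.risk_model <- function(object, features, ...) {
  dat <- as.data.frame(features[feature_cols()])
  as.integer(as.character(predict(object$tree, dat, type = "class")))
}

#' Serialise a risk model's structure to JSON
#'
#' Writes the tree frame (splits, thresholds, leaf labels) and training
#' metadata so a fitted model can be audited outside R.
#'
#' @param model a `risk_model`.
#' @param path output JSON path.
#' @export
write_risk_model <- function(model, path) {
  fr <- model$tree$frame
  splits <- model$tree$splits
  jsonlite::write_json(list(
    schema_version = SCHEMA_VERSION,
    chosen = model$chosen,
    cv = model$cv,
    frame = data.frame(var = as.character(fr$var), n = fr$n,
                       yval = fr$yval, row.names = NULL),
    splits = if (!is.null(splits)) as.data.frame(cbind(var = rownames(splits), as.data.frame(splits))) else NULL
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Evaluate a classifier against annotated labels
#'
#' Builds the 2x2 confusion matrix (predicted x actual), the overall
#' accuracy, and the *all-warnings baseline*: the precision achieved by
#' the raw automotive sensor, which treats every warning as a risk, i.e.
#' the fraction of actual risks among all warnings.
#'
#' @param predicted,actual 0/1 vectors of equal, nonzero length.
#' @return List: `confusion` (2x2 matrix, rows = predicted, cols =
#'   actual), `accuracy_pct`, `baseline_pct`, `n`.
#' @examples
#' ev <- evaluate_predictions(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' ev$accuracy_pct
#' @export
evaluate_predictions <- function(predicted, actual) {
  if (length(predicted) == 0) stop_("empty test set")
  if (length(predicted) != length(actual)) stop_("predicted/actual lengths differ")
  if (!all(predicted %in% c(0, 1)) || !all(actual %in% c(0, 1)))
    stop_("labels must be binary 0/1")
  cm <- table(factor(predicted, levels = c(1, 0)), factor(actual, levels = c(1, 0)))
  dimnames(cm) <- list(predicted = c("risk", "no_risk"), actual = c("risk", "no_risk"))
  confusion_summary(cm)
}

#' Summarise a 2x2 confusion matrix
#'
#' @param confusion 2x2 matrix, rows = predicted (risk, no-risk), cols =
#'   actual (risk, no-risk).
#' @return List with `confusion`, `accuracy_pct` = 100 (TP+TN)/N,
#'   `baseline_pct` = 100 (actual positives)/N, `n`.
#' @examples
#' confusion_summary(matrix(c(4, 2, 2, 17), 2, byrow = TRUE))
#' @export
confusion_summary <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(all(dim(confusion) == c(2, 2)), all(confusion >= 0))
  n <- sum(confusion)
  if (n == 0) stop_("empty confusion matrix")
  list(confusion = confusion,
       accuracy_pct = 100 * (confusion[1, 1] + confusion[2, 2]) / n,
       baseline_pct = 100 * sum(confusion[, 1]) / n,
       n = n)
}

#' Daily collision-risk index for one driver-day
#'
#' `R` risk-classified events over `WT` driving hours give the per-hour
#' index `R_1hr = R / WT`. Days with under 3 h of driving are flagged
#' excluded (`included = FALSE`) and their index is withheld from any
#' analysis.
#'
#' @param labels 0/1 event labels for the day (may be empty: no alarms).
#' @param wt_hours driving duration (h), must be > 0.
#' @param min_hours inclusion threshold (default 3 h).
#' @return One-row tibble: `R`, `n_events`, `wt_hours`, `r_1hr`, `included`.
#' @export
daily_index <- function(labels, wt_hours, min_hours = 3) {
  if (wt_hours <= 0) stop_("wt_hours must be > 0 (got %g)", wt_hours)
  if (length(labels) > 0 && !all(labels %in% c(0, 1))) stop_("labels must be binary 0/1")
  r <- sum(labels == 1)
  included <- wt_hours >= min_hours
  tibble(R = r, n_events = length(labels), wt_hours = wt_hours,
         r_1hr = if (included) r / wt_hours else NA_real_,
         included = included)
}

#' Daily risk table for a cohort
#'
#' Classifies every event (reference rules by default, or a trained
#' `risk_model`) and aggregates to driver-day rows, joining driving
#' hours from the cohort table. Driver-days without any warning get
#' `R = 0` and `n_events = 0`.
#'
#' @param events nested event tibble (`driver_id`, `date`, `event_id`,
#'   `speeds`, optional `duration_s`).
#' @param cohort tibble with `driver_id`, `date`, `wt_hours`.
#' @param classifier `"rules"` or a `risk_model`.
#' @param min_hours inclusion threshold (h).
#' @return Tibble: `driver_id`, `date`, `R`, `n_events`, `wt_hours`,
#'   `r_1hr`, `included`.
#' @export
daily_risk_table <- function(events, cohort, classifier = "rules", min_hours = 3) {
  if (any(cohort$wt_hours <= 0)) stop_("wt_hours must be > 0 for every driver-day")
  if (nrow(events) > 0) {
    feats <- event_features(events)
    feats$label <- if (identical(classifier, "rules")) rule_classify(feats)
                   else predict(classifier, feats)
    day_counts <- feats %>%
      group_by(.data$driver_id, .data$date) %>%
      summarise(R = sum(.data$label == 1), n_events = dplyr::n(), .groups = "drop")
  } else {
    day_counts <- tibble(driver_id = character(), date = as.Date(character()),
                         R = integer(), n_events = integer())
  }
  cohort %>%
    select("driver_id", "date", "wt_hours") %>%
    left_join(day_counts, by = c("driver_id", "date")) %>%
    mutate(
      R = ifelse(is.na(.data$R), 0L, .data$R),
      n_events = ifelse(is.na(.data$n_events), 0L, .data$n_events),
      included = .data$wt_hours >= min_hours,
      r_1hr = ifelse(.data$included, .data$R / .data$wt_hours, NA_real_)
    ) %>%
    select("driver_id", "date", "R", "n_events", "wt_hours", "r_1hr", "included")
}
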