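#' Assemble per-driver-day analysis records
#'
#' Joins the three measurement streams — HRV summaries (pre/post), daily
#' risk indices, and VAS ratings — into one row per driver-day, and adds
#' previous-day lagged copies of the post-shift measures. "Previous day"
#' means the previous *calendar* date with an accepted post-shift
#' recording; a gap yields `NA`, never a carried-forward value.
#'
#' Two study-level exclusions are flagged (not silently dropped):
#' drivers whose VAS never moved from a single value across the whole
#' study (`excluded_vas`), and drivers whose alarm never sounded on any
#' day (`excluded_no_warnings`). `analysis_ready` combines the flags
#' with day-level inclusion (driving >= 3 h) and QC acceptance of both
#' the day's recordings; only `analysis_ready` rows enter any statistic.
#'
#' @param hrv_table output of [summarize_hrv()].
#' @param daily_table output of [daily_risk_table()].
#' @param vas_table tibble with `driver_id`, `date`, `vas_pre`, `vas_post`.
#' @return Tibble of analysis records, one row per driver-day.
#' @export
build_records <- function(hrv_table, daily_table, vas_table) {
  dup <- hrv_table %>% count(.data$driver_id, .data$date, .data$condition) %>% filter(n > 1)
  if (nrow(dup) > 0)
    stop_("duplicate (driver, date, condition) keys in hrv_table, e.g. %s %s %s",
          dup$driver_id[1], format(dup$date[1]), dup$condition[1])
  for (tb in list(daily_table, vas_table)) {
    d2 <- tb %>% count(.data$driver_id, .data$date) %>% filter(n > 1)
    if (nrow(d2) > 0)
      stop_("duplicate (driver, date) keys, e.g. %s %s", d2$driver_id[1], format(d2$date[1]))
  }

  hrv_wide <- hrv_table %>%
    select("driver_id", "date", "condition", "accepted",
           "lf_score", "lf_hf") %>%
    tidyr::pivot_wider(names_from = "condition",
                       values_from = c("accepted", "lf_score", "lf_hf")) %>%
    rename(accepted_pre = "accepted_pre_shift", accepted_post = "accepted_post_shift",
           lf_score_pre = "lf_score_pre_shift", lf_score_post = "lf_score_post_shift",
           lf_hf_pre = "lf_hf_pre_shift", lf_hf_post = "lf_hf_post_shift")

  rec <- daily_table %>%
    inner_join(hrv_wide, by = c("driver_id", "date")) %>%
    inner_join(vas_table, by = c("driver_id", "date"))

  # previous-calendar-day post-shift measures (accepted recordings only)
  prev <- hrv_wide %>%
    filter(.data$accepted_post) %>%
    mutate(date = .data$date + 1) %>%
    select("driver_id", "date",
           lf_score_post_prev = "lf_score_post", lf_hf_post_prev = "lf_hf_post")
  rec <- left_join(rec, prev, by = c("driver_id", "date"))

  vas_flat <- vas_table %>%
    tidyr::pivot_longer(c("vas_pre", "vas_post"), values_to = "vas")
  vas_invariant <- vas_flat %>%
    group_by(.data$driver_id) %>%
    summarise(excluded_vas = dplyr::n_distinct(.data$vas) == 1, .groups = "drop")
  no_warn <- daily_table %>%
    group_by(.data$driver_id) %>%
    summarise(excluded_no_warnings = sum(.data$n_events) == 0, .groups = "drop")

  rec %>%
    left_join(vas_invariant, by = "driver_id") %>%
    left_join(no_warn, by = "driver_id") %>%
    mutate(analysis_ready = .data$included & .data$accepted_pre & .data$accepted_post &
             !.data$excluded_vas & !.data$excluded_no_warnings)
}

#' Pearson correlation with two-sided p-value
#'
#' Pairwise-complete Pearson product-moment correlation; the p-value
#' comes from the t distribution with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length.
#' @return A `correlation_result` list: `r`, `p`, `n`.
#' @examples
#' correlate(1:10, 2 * (1:10) + 1)$r # exactly 1
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) stop_("x and y lengths differ")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop_("need at least 3 complete pairs, got %d", length(x))
  if (var(x) == 0 || var(y) == 0)
    stop_("zero variance: correlation undefined")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = length(x)),
            class = "correlation_result")
}

#' Median-split group comparison (Welch's t-test)
#'
#' Splits driver-days at the median of `split_field` (ties at the median
#' go to the low group: high is strictly greater, low is less than or
#' equal), screens each group's values with the Shapiro-Wilk test, and
#' compares group means with Welch's unequal-variance two-sided t-test
#' at the 5% level. The Shapiro-Wilk p-values are reported but never
#' gate the t-test.
#'
#' @param records analysis-record tibble (or any tibble).
#' @param value_field column compared between groups.
#' @param split_field column whose median defines the groups
#'   (default `"r_1hr"`).
#' @return A `group_comparison` list: `threshold`, `n_high`, `n_low`,
#'   `mean_high`, `mean_low`, `sd_high`, `sd_low`, `t`, `df`, `p`,
#'   `shapiro_p_high`, `shapiro_p_low`, `alpha`.
#' @export
median_split_test <- function(records, value_field, split_field = "r_1hr") {
  s <- records[[split_field]]; v <- records[[value_field]]
  ok <- is.finite(s) & is.finite(v)
  s <- s[ok]; v <- v[ok]
  if (length(s) < 4) stop_("need at least 4 complete records for a median split")
  if (min(s) == max(s)) stop_("degenerate split: all '%s' values equal", split_field)
  thr <- median(s)
  hi <- v[s > thr]; lo <- v[s <= thr]
  if (length(hi) < 2 || length(lo) < 2)
    stop_("median split leaves fewer than 2 records on one side")
  tt <- t.test(hi, lo, var.equal = FALSE, alternative = "two.sided")
  shap <- function(g) {
    if (length(g) < 3 || length(unique(g)) == 1) return(NA_real_)
    shapiro.test(g[seq_len(min(length(g), 5000))])$p.value
  }
  structure(list(
    threshold = thr, n_high = length(hi), n_low = length(lo),
    mean_high = mean(hi), mean_low = mean(lo),
    sd_high = sd(hi), sd_low = sd(lo),
    t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
    shapiro_p_high = shap(hi), shapiro_p_low = shap(lo), alpha = 0.05
  ), class = "group_comparison")
}

#' Fatigue-risk association analysis
#'
#' Runs the full association battery on analysis-ready records: Pearson
#' correlations of the daily collision-risk index `R_1hr` with the VAS
#' fatigue ratings, the LF deviation scores and the LF/HF ratios (same
#' day pre/post and previous-day post-shift), plus the median-split
#' Welch comparison of the previous-day post-shift LF score between
#' high- and low-risk days. No multiple-testing correction is applied;
#' `n_tests` annotates how many tests were run.
#'
#' @param records output of [build_records()].
#' @return List: `correlations` (named list of `correlation_result`),
#'   `group_comparison`, `n_records`, `n_tests`.
#' @export
run_association <- function(records) {
  use <- filter(records, .data$analysis_ready)
  if (nrow(use) < 3) stop_("fewer than 3 analysis-ready records")
  pairs <- c(vas_pre = "vas_pre", vas_post = "vas_post",
             lf_score_pre = "lf_score_pre", lf_hf_pre = "lf_hf_pre",
             lf_score_post_prev = "lf_score_post_prev",
             lf_hf_post_prev = "lf_hf_post_prev")
  cors <- lapply(pairs, function(col) {
    tryCatch(correlate(use[[col]], use$r_1hr), error = function(e) NULL)
  })
  comp <- tryCatch(
    median_split_test(use, "lf_score_post_prev", "r_1hr"),
    error = function(e) NULL
  )
  list(correlations = cors, group_comparison = comp,
       n_records = nrow(use),
       n_tests = sum(!vapply(cors, is.null, logical(1))) + !is.null(comp))
}

#' Cross-day lagged LF-score pairs
#'
#' Pairs each accepted post-shift LF deviation score on day d with the
#' accepted pre-shift score of the same driver on calendar day d+1 —
#' the lag along which next-day carry-over of fatigue is quantified.
#'
#' @param hrv_table output of [summarize_hrv()].
#' @return Tibble: `driver_id`, `date` (the pre-shift day),
#'   `lf_score_post_prev`, `lf_score_pre`.
#' @export
crossday_pairs <- function(hrv_table) {
  pre <- hrv_table %>%
    filter(.data$condition == "pre_shift", .data$accepted, is.finite(.data$lf_score)) %>%
    select("driver_id", "date", lf_score_pre = "lf_score")
  post <- hrv_table %>%
    filter(.data$condition == "post_shift", .data$accepted, is.finite(.data$lf_score)) %>%
    mutate(date = .data$date + 1) %>%
    select("driver_id", "date", lf_score_post_prev = "lf_score")
  inner_join(post, pre, by = c("driver_id", "date")) %>%
    arrange(.data$driver_id, .data$date)
}
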