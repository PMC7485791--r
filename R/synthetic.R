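#' Specification of a synthetic driver cohort
#'
#' Collects every parameter of the synthetic study. The defaults mirror
#' the study conditions the analysis assumes: 33 drivers aged 24-65
#' observed daily pre- and post-shift, a cross-day correlation of 0.29
#' between the post-shift LF deviation score and the next morning's
#' pre-shift score, and a median daily risk rate near 3.2 events per
#' driving hour.
#'
#' @param n_drivers number of drivers (>= 1).
#' @param n_days number of consecutive study days (>= 2; the cross-day
#'   lag needs at least two).
#' @param age_range driver age range in years, drawn uniformly.
#' @param seed root integer seed; every random draw flows from it.
#' @param rho_crossday lag-1 correlation, in [-1, 1], of the post-shift
#'   latent fatigue with the next day's pre-shift latent (and hence of
#'   the LF deviation scores).
#' @param beta_risk log-linear slope linking the previous day's
#'   post-shift latent fatigue (in SD units) to the expected risk-event
#'   rate; 0 decouples fatigue from risk.
#' @param label_noise probability, in [0, 1], that an event's emitted
#'   label is flipped relative to its rule-derived truth.
#' @param mean_wt_hours mean daily driving duration (h).
#' @param wt_sdlog log-scale SD of the lognormal driving-hours draw.
#' @param base_risk_rate expected risk events per driving hour at
#'   average fatigue (calibrated so the cohort median daily index sits
#'   near 3.2 events/h).
#' @param nonrisk_rate expected non-risk warnings per driving hour.
#' @param mean_rri_ms,rri_between_sd_ms cohort mean beat interval and
#'   its between-driver SD (ms).
#' @param rri_noise_sd_ms white beat-to-beat noise SD (ms) added to each
#'   recording.
#' @param hf_mu,hf_sigma log-scale location/SD of HF power relative to
#'   the mean interval (HF = RRI_average * exp(hf_mu + hf_sigma * z)).
#' @param vas_base,vas_slope,vas_noise_sd affine coupling of the VAS
#'   fatigue rating (0-100) to the latent fatigue, plus rating noise.
#' @param margin sampling margin (feature units) kept between event
#'   features and the rule thresholds; for the narrow speed-deviation
#'   interval the margin is capped at 20% of the interval width.
#' @param lf_freq_hz,hf_freq_hz centre frequencies of the LF and HF
#'   modulation in generated recordings.
#' @param duration_s length of each resting recording (s).
#' @param norms `norm_table` used as the generator's reference
#'   population (also the default scoring table).
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_drivers = 33, n_days = 18, age_range = c(24, 65),
                        seed = 1, rho_crossday = 0.29, beta_risk = 0.1,
                        label_noise = 0.05, mean_wt_hours = 8,
                        wt_sdlog = 0.4, base_risk_rate = 3.2,
                        nonrisk_rate = 1.5, mean_rri_ms = 800,
                        rri_between_sd_ms = 50, rri_noise_sd_ms = 5,
                        hf_mu = -1.0, hf_sigma = 0.5,
                        vas_base = 40, vas_slope = 8, vas_noise_sd = 12,
                        margin = 1, lf_freq_hz = 0.10, hf_freq_hz = 0.25,
                        duration_s = 90, norms = default_norm_table()) {
  if (n_drivers < 1) stop_("n_drivers must be >= 1")
  if (n_days < 2) stop_("n_days must be >= 2 (cross-day lag needs two days)")
  if (abs(rho_crossday) > 1) stop_("|rho_crossday| must be <= 1")
  if (label_noise < 0 || label_noise > 1) stop_("label_noise must be in [0, 1]")
  if (length(age_range) != 2 || age_range[1] > age_range[2]) stop_("bad age_range")
  if (mean_wt_hours <= 0 || base_risk_rate < 0 || nonrisk_rate < 0)
    stop_("rates and driving hours must be nonnegative")
  spec <- as.list(environment())
  structure(spec, class = "cohort_spec")
}

#' Generate a synthetic resting RR-interval recording
#'
#' Beat intervals follow additive sinusoidal modulation of the interval
#' series: the instantaneous interval at beat time `t` is
#' `mean_rri_ms + lf_amp*sin(2*pi*lf_freq*t + phase_lf) +
#' hf_amp*sin(2*pi*hf_freq*t + phase_hf) + N(0, noise_sd^2)`, and the
#' next beat occurs that many milliseconds later. A pure sinusoid of
#' amplitude A contributes band power A^2/2 (ms^2), which gives every
#' spectral stage an analytic oracle.
#'
#' @param duration_s recording length (s); the series spans at least
#'   this long.
#' @param mean_rri_ms mean beat interval, in [300, 2000] ms.
#' @param lf_amp_ms,hf_amp_ms modulation amplitudes (ms).
#' @param lf_freq_hz LF modulation frequency, in [0.04, 0.15) Hz.
#' @param hf_freq_hz HF modulation frequency, in [0.15, 0.4] Hz.
#' @param noise_sd_ms white beat-to-beat noise SD (ms).
#' @param phase_lf,phase_hf modulation phases (rad).
#' @param seed optional seed; `NULL` consumes the ambient RNG stream.
#' @return Numeric vector of beat intervals (ms).
#' @examples
#' rri <- generate_rri(90, 800, lf_amp_ms = 30, hf_amp_ms = 0)
#' sum(rri) / 1000 >= 90
#' @export
generate_rri <- function(duration_s, mean_rri_ms, lf_amp_ms = 0, hf_amp_ms = 0,
                         lf_freq_hz = 0.10, hf_freq_hz = 0.25,
                         noise_sd_ms = 0, phase_lf = 0, phase_hf = 0,
                         seed = NULL) {
  if (!(lf_freq_hz >= 0.04 && lf_freq_hz < 0.15))
    stop_("lf_freq_hz must lie in [0.04, 0.15) Hz, got %g", lf_freq_hz)
  if (!(hf_freq_hz >= 0.15 && hf_freq_hz <= 0.4))
    stop_("hf_freq_hz must lie in [0.15, 0.4] Hz, got %g", hf_freq_hz)
  if (mean_rri_ms < 300 || mean_rri_ms > 2000)
    stop_("mean_rri_ms must lie in [300, 2000] ms, got %g", mean_rri_ms)
  if (duration_s <= 0) stop_("duration_s must be > 0")
  with_seed_(seed, {
    n_max <- ceiling(duration_s * 1000 / (mean_rri_ms - lf_amp_ms - hf_amp_ms)) + 8L
    noise <- if (noise_sd_ms > 0) rnorm(n_max, 0, noise_sd_ms) else numeric(n_max)
    out <- numeric(n_max)
    t <- 0; i <- 0L
    while (t < duration_s) {
      i <- i + 1L
      iv <- mean_rri_ms +
        lf_amp_ms * sin(2 * pi * lf_freq_hz * t + phase_lf) +
        hf_amp_ms * sin(2 * pi * hf_freq_hz * t + phase_hf) + noise[i]
      if (iv <= 0) iv <- 1  # pathological amplitudes: keep time advancing
      out[i] <- iv
      t <- t + iv / 1000
    }
    out[seq_len(i)]
  })
}

# ---- event-feature region sampling ------------------------------------

# Feature regions stay `margin` units away from every rule threshold
# (capped at 20% of the interval width for the narrow speed-deviation
# window) so classifier tests are never decided by boundary ties.
# Beyond the per-threshold margin, regions are designed so that every
# boundary between class-conditional supports sits in a feature gap no
# region occupies: minimum speed is drawn from the *same* range for all
# four highway-speed regions (so it carries no accidental class
# information), speeds below ~30 km/h occur only in congested-risk
# events, the deviation supports leave a buffer around 5.8/6.5, and the
# duration supports leave buffers around 42.5 and 79.0. A greedy CART's
# learned thresholds therefore always land in unoccupied gaps and
# generalize exactly to fresh margin-sampled events.
event_regions <- function(margin = 1) {
  dev_m <- min(margin * 0.14, 0.2 * (6.5 - 5.8))
  list(
    # risk min-speed range nested strictly inside the non-risk ranges so
    # an extreme-order-statistic speed value can never be a risk event
    # (stops cp=0 CART from chasing edge singletons outside the gaps)
    risk_highway = list(dur = c(ceiling(79 + margin + 1), 120),
                        min = c(40, 54), dev = c(5.8 + dev_m, 6.5 - dev_m)),
    risk_congest = list(dur = c(ceiling(42.5 + margin + 1), 78),
                        min = c(16, 22), dev = c(1.5, 2.5)),
    non_short    = list(dur = c(5, floor(42.5 - margin)),
                        min = c(39, 55), dev = c(2, 3.3)),
    non_long_fast = list(dur = c(ceiling(79 + margin + 1), 120),
                         min = c(39, 55), dev = c(2, 5.8 - margin * 0.5)),
    non_mid_fast = list(dur = c(ceiling(42.5 + margin + 1), 78),
                        min = c(39, 55), dev = c(3, 5))
  )
}

# One speed profile whose features land inside `reg`; consumes ambient
# RNG. The shape is a sample-standardized sinusoid anchored at the
# drawn minimum speed, so speed_deviation and min_speed hit their
# targets exactly and the max stays within dev * range(shape) (~2.8 SD)
# of the minimum — the deterministic bounds the support-gap argument
# above relies on.
sample_event_profile <- function(reg) {
  n <- sample(reg$dur[1]:reg$dur[2], 1)
  mn <- runif(1, reg$min[1], reg$min[2])
  dev <- runif(1, reg$dev[1], reg$dev[2])
  k <- sample(1:3, 1)
  shape <- sin(2 * pi * k * seq_len(n) / n + runif(1, 0, 2 * pi))
  shape <- (shape - mean(shape)) / sd(shape)
  mn + dev * (shape - min(shape))
}

#' Generate labelled synthetic warning events
#'
#' Risk events are sampled from feature regions where the reference
#' rules fire (split between the sustained-highway and congested
#' low-speed situations); non-risk events from regions where both rules
#' fail. Each emitted label is then flipped with probability
#' `label_noise`, emulating annotation noise; the pre-noise rule label
#' is kept alongside as truth.
#'
#' @param n_events number of events (0 gives an empty table).
#' @param risk_fraction probability that an event is drawn from a risk
#'   region, in [0, 1].
#' @param label_noise per-event label-flip probability.
#' @param seed optional seed (`NULL`: ambient stream).
#' @param margin sampling margin from the rule thresholds.
#' @return Nested tibble: `event_id`, `duration_s`, `speeds`
#'   (list-column), `label` (emitted), `label_true` (rule label before
#'   noise), `region`.
#' @export
generate_events <- function(n_events, risk_fraction, label_noise = 0,
                            seed = NULL, margin = 1) {
  if (risk_fraction < 0 || risk_fraction > 1) stop_("risk_fraction must be in [0, 1]")
  if (label_noise < 0 || label_noise > 1) stop_("label_noise must be in [0, 1]")
  regs <- event_regions(margin)
  empty <- tibble(event_id = integer(), duration_s = integer(),
                  speeds = list(), label = integer(), label_true = integer(),
                  region = character())
  if (n_events == 0) return(empty)
  with_seed_(seed, {
    is_risk <- runif(n_events) < risk_fraction
    region <- ifelse(is_risk,
                     sample(c("risk_highway", "risk_congest"), n_events, replace = TRUE),
                     sample(c("non_short", "non_long_fast", "non_mid_fast"),
                            n_events, replace = TRUE))
    speeds <- vector("list", n_events)
    for (i in seq_len(n_events)) speeds[[i]] <- sample_event_profile(regs[[region[i]]])
    ev <- tibble(event_id = seq_len(n_events),
                 duration_s = lengths(speeds), speeds = speeds, region = region)
    truth <- rule_classify(event_features(ev))
    flip <- runif(n_events) < label_noise
    ev$label_true <- truth
    ev$label <- ifelse(flip, 1L - truth, truth)
    ev[c("event_id", "duration_s", "speeds", "label", "label_true", "region")]
  })
}

#' Generate a full synthetic cohort with ground truth
#'
#' Emits, per driver per study day, pre- and post-shift resting RRI
#' recordings, VAS fatigue ratings, driving hours, and warning events —
#' together with truth tables recording the latent quantities each
#' record was generated from.
#'
#' The statistical structure: each driver carries a latent fatigue
#' process z over consecutive half-day measurement occasions (pre_1,
#' post_1, pre_2, ...), AR(1) with coefficient `rho_crossday` and
#' standard-normal marginals, so adjacent occasions — in particular the
#' post-shift of day d and the pre-shift of day d+1 — correlate at
#' exactly `rho_crossday`. The recording's LF power is set to
#' `RRI_average * exp(mu_LF(age) + sigma_LF(age) * z)` so the LF
#' deviation score equals `50 + 10 z` up to spectral-estimation error.
#' VAS couples affinely to z; the expected risk-event rate on day d is
#' `base_risk_rate * exp(beta_risk * z_post(d-1))` per driving hour
#' (day 1 uses one extra pre-study latent step).
#'
#' @param spec a [cohort_spec()].
#' @param events generate warning events (`TRUE`); `FALSE` skips the
#'   event stream for HRV-only studies.
#' @return A `fatigue_cohort` list: `drivers`, `cohort` (driver-day VAS
#'   and hours), `recordings` (nested RRI), `events` (nested), and
#'   `truth` (`recordings`, `events`, `days`). All tables are keyed by
#'   `driver_id`/`date`(/`condition`/`event_id`) and align one-to-one
#'   with their truth rows.
#' @export
generate_cohort <- function(spec = cohort_spec(), events = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  # named sub-seeds drawn once from the root: each generation stream is
  # reseeded independently so e.g. toggling `events` cannot perturb HRV draws
  sub <- sample.int(.Machine$integer.max - 1, 5)
  names(sub) <- c("drivers", "latent", "recordings", "cohort", "events")

  dates <- as.Date("2019-04-01") + seq_len(spec$n_days) - 1

  drivers <- with_seed_(sub[["drivers"]], tibble(
    driver_id = sprintf("D%02d", seq_len(spec$n_drivers)),
    age = floor(runif(spec$n_drivers, spec$age_range[1], spec$age_range[2] + 1)),
    sex = sample(c("F", "M"), spec$n_drivers, replace = TRUE, prob = c(0.06, 0.94)),
    mean_rri_ms = pmin(pmax(rnorm(spec$n_drivers, spec$mean_rri_ms,
                                  spec$rri_between_sd_ms), 650), 1100)
  ))

  # latent fatigue: 2*n_days occasions + 1 pre-study step, AR(1)
  n_occ <- 2 * spec$n_days + 1
  lat <- with_seed_(sub[["latent"]], {
    rho <- spec$rho_crossday
    t(vapply(seq_len(spec$n_drivers), function(d) {
      z <- numeric(n_occ)
      z[1] <- rnorm(1)
      for (k in 2:n_occ) z[k] <- rho * z[k - 1] + sqrt(1 - rho^2) * rnorm(1)
      z
    }, numeric(n_occ)))
  })
  # occasion index: 1 = pre-study; day d pre -> 2d, post -> 2d + 1
  z_pre <- lat[, 2 * seq_len(spec$n_days), drop = FALSE]
  z_post <- lat[, 2 * seq_len(spec$n_days) + 1, drop = FALSE]
  z_post_prev <- cbind(lat[, 1], z_post[, -spec$n_days, drop = FALSE])

  key <- tidyr::expand_grid(driver = seq_len(spec$n_drivers), day = seq_len(spec$n_days))

  recordings <- with_seed_(sub[["recordings"]], {
    rec_key <- tidyr::expand_grid(key, condition = c("pre_shift", "post_shift"))
    ns <- norm_lookup(spec$norms, drivers$age[rec_key$driver])
    z <- ifelse(rec_key$condition == "pre_shift",
                z_pre[cbind(rec_key$driver, rec_key$day)],
                z_post[cbind(rec_key$driver, rec_key$day)])
    rri_mean <- drivers$mean_rri_ms[rec_key$driver]
    lf_true <- rri_mean * exp(ns$mu + ns$sigma * z)
    hf_true <- rri_mean * exp(spec$hf_mu + spec$hf_sigma * rnorm(nrow(rec_key)))
    ph <- matrix(runif(2 * nrow(rec_key), 0, 2 * pi), ncol = 2)
    ivs <- vector("list", nrow(rec_key))
    for (i in seq_len(nrow(rec_key))) {
      ivs[[i]] <- generate_rri(spec$duration_s, rri_mean[i],
                               lf_amp_ms = sqrt(2 * lf_true[i]),
                               hf_amp_ms = sqrt(2 * hf_true[i]),
                               lf_freq_hz = spec$lf_freq_hz,
                               hf_freq_hz = spec$hf_freq_hz,
                               noise_sd_ms = spec$rri_noise_sd_ms,
                               phase_lf = ph[i, 1], phase_hf = ph[i, 2])
    }
    tibble(driver_id = drivers$driver_id[rec_key$driver],
           date = dates[rec_key$day], condition = rec_key$condition,
           intervals = ivs, z_true = z, lf_true = lf_true, hf_true = hf_true)
  })

  cohort <- with_seed_(sub[["cohort"]], {
    wt <- rlnorm(nrow(key), log(spec$mean_wt_hours) - spec$wt_sdlog^2 / 2,
                 spec$wt_sdlog)
    zp <- z_pre[cbind(key$driver, key$day)]
    zq <- z_post[cbind(key$driver, key$day)]
    vas <- function(z) pmin(pmax(round(
      spec$vas_base + spec$vas_slope * z + rnorm(length(z), 0, spec$vas_noise_sd)
    ), 0), 100)
    tibble(driver_id = drivers$driver_id[key$driver], date = dates[key$day],
           wt_hours = round(wt, 2), vas_pre = vas(zp), vas_post = vas(zq))
  })

  zpp <- z_post_prev[cbind(key$driver, key$day)]
  truth_days <- tibble(
    driver_id = drivers$driver_id[key$driver], date = dates[key$day],
    z_post_prev = zpp,
    risk_rate_true = spec$base_risk_rate * exp(spec$beta_risk * zpp)
  )

  ev_tbl <- NULL; truth_events <- NULL
  if (events) {
    ev_tbl <- with_seed_(sub[["events"]], {
      regs <- event_regions(spec$margin)
      n_risk <- rpois(nrow(key), truth_days$risk_rate_true * cohort$wt_hours)
      n_non <- rpois(nrow(key), spec$nonrisk_rate * cohort$wt_hours)
      n_ev <- n_risk + n_non
      day_of <- rep(seq_len(nrow(key)), n_ev)
      # risk/non-risk counts are fixed per day; region type and ordering random
      region <- unlist(lapply(seq_len(nrow(key)), function(i) {
        r <- c(sample(c("risk_highway", "risk_congest"), n_risk[i], replace = TRUE),
               sample(c("non_short", "non_long_fast", "non_mid_fast"),
                      n_non[i], replace = TRUE))
        if (length(r) > 1) sample(r) else r
      }))
      speeds <- lapply(region, function(r) sample_event_profile(regs[[r]]))
      seq_in_day <- unlist(lapply(n_ev, seq_len))
      ev <- tibble(
        driver_id = cohort$driver_id[day_of], date = cohort$date[day_of],
        event_id = sprintf("%s_%s_e%02d", cohort$driver_id[day_of],
                           format(cohort$date[day_of], "%Y%m%d"), seq_in_day),
        start_time = sprintf("%02d:%02d:%02d",
                             pmin(6 + floor(runif(length(day_of), 0,
                                                  cohort$wt_hours[day_of])), 23),
                             sample(0:59, length(day_of), replace = TRUE),
                             sample(0:59, length(day_of), replace = TRUE)),
        duration_s = lengths(speeds), speeds = speeds, region = region)
      if (nrow(ev) > 0) {
        truth <- rule_classify(event_features(ev))
        flip <- runif(nrow(ev)) < spec$label_noise
        ev$label_true <- truth
        ev$label <- ifelse(flip, 1L - truth, truth)
      } else {
        ev$label_true <- integer(0); ev$label <- integer(0)
      }
      ev
    })
    truth_events <- select(ev_tbl, "driver_id", "date", "event_id",
                           "region", "label_true")
  }

  structure(list(
    spec = spec,
    drivers = drivers,
    cohort = cohort,
    recordings = select(recordings, "driver_id", "date", "condition", "intervals"),
    events = if (events) select(ev_tbl, "driver_id", "date", "event_id",
                                "start_time", "duration_s", "speeds", "label")
             else NULL,
    truth = list(
      recordings = select(recordings, "driver_id", "date", "condition",
                          "z_true", "lf_true", "hf_true"),
      events = truth_events,
      days = truth_days
    )
  ), class = "fatigue_cohort")
}

#' Long-format RRI table for a cohort
#'
#' Unnests the per-recording interval vectors into the `rri.csv` dialect
#' (`driver_id`, `date`, `condition`, `beat_index`, `rri_ms`).
#'
#' @param cohort a `fatigue_cohort`.
#' @return Long tibble, one row per beat.
#' @export
cohort_rri_long <- function(cohort) {
  rec <- cohort$recordings
  n <- lengths(rec$intervals)
  tibble(
    driver_id = rep(rec$driver_id, n),
    date = rep(rec$date, n),
    condition = rep(rec$condition, n),
    beat_index = unlist(lapply(n, seq_len)),
    rri_ms = unlist(rec$intervals)
  )
}

#' Long-format event table for a cohort
#'
#' Unnests speed samples into the `events.csv` dialect (`driver_id`,
#' `date`, `event_id`, `start_time`, `sample_index`, `speed_kmh`).
#'
#' @param events nested event tibble (e.g. `cohort$events`).
#' @return Long tibble, one row per 1-Hz speed sample.
#' @export
events_to_long <- function(events) {
  n <- lengths(events$speeds)
  tibble(
    driver_id = rep(events$driver_id, n),
    date = rep(events$date, n),
    event_id = rep(events$event_id, n),
    start_time = rep(events$start_time, n),
    sample_index = unlist(lapply(n, seq_len)),
    speed_kmh = unlist(events$speeds)
  )
}

#' Nest a long event table back into per-event speed vectors
#'
#' @param events_long tibble in the `events.csv` dialect.
#' @return Nested tibble with a `speeds` list-column and `duration_s`.
#' @export
events_from_long <- function(events_long) {
  events_long %>%
    arrange(.data$driver_id, .data$date, .data$event_id, .data$sample_index) %>%
    group_by(.data$driver_id, .data$date, .data$event_id, .data$start_time) %>%
    summarise(speeds = list(.data$speed_kmh), .groups = "drop") %>%
    mutate(duration_s = lengths(.data$speeds))
}
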