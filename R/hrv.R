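#' Quality-control policy for RR-interval recordings
#'
#' A recording is unusable when too many beats are artefactual
#' (mis-detected R waves, ectopy, movement). A beat interval is flagged
#' when it falls outside a physiological range or jumps too far from the
#' previous accepted interval; the whole recording is rejected when the
#' flagged fraction *exceeds* `max_flagged_fraction` (exactly at the
#' threshold is still accepted).
#'
#' @param min_rri_ms,max_rri_ms physiological interval range (ms).
#' @param max_rel_change maximum allowed relative change from the previous
#'   accepted interval (0.2 = 20%).
#' @param max_flagged_fraction rejection threshold on the flagged fraction.
#' @return A `qc_policy` list.
#' @export
qc_policy <- function(min_rri_ms = 300, max_rri_ms = 2000,
                      max_rel_change = 0.20, max_flagged_fraction = 0.10) {
  stopifnot(min_rri_ms > 0, max_rri_ms > min_rri_ms,
            max_rel_change > 0, max_flagged_fraction >= 0)
  structure(list(min_rri_ms = min_rri_ms, max_rri_ms = max_rri_ms,
                 max_rel_change = max_rel_change,
                 max_flagged_fraction = max_flagged_fraction),
            class = "qc_policy")
}

#' Quality-control an RR-interval series
#'
#' @param intervals numeric vector of beat intervals (ms), in order.
#' @param policy a [qc_policy()].
#' @return A one-row tibble: `n_beats`, `n_flagged`, `flagged_fraction`,
#'   `accepted`. Rejection (`accepted = FALSE`) is distinct from an
#'   error: an empty series is an error, not a rejection.
#' @examples
#' qc_rri(rep(800, 112))
#' @export
qc_rri <- function(intervals, policy = qc_policy()) {
  flagged <- qc_flags(intervals, policy)
  frac <- mean(flagged)
  tibble(n_beats = length(intervals), n_flagged = sum(flagged),
         flagged_fraction = frac,
         accepted = frac <= policy$max_flagged_fraction)
}

qc_flags <- function(intervals, policy) {
  if (length(intervals) == 0) stop_("empty RRI series: nothing to quality-control")
  if (any(!is.finite(intervals))) stop_("RRI series contains non-finite values")
  flagged <- logical(length(intervals))
  last_ok <- NA_real_
  for (i in seq_along(intervals)) {
    x <- intervals[i]
    bad <- x < policy$min_rri_ms || x > policy$max_rri_ms
    if (!bad && !is.na(last_ok) && abs(x - last_ok) / last_ok > policy$max_rel_change)
      bad <- TRUE
    flagged[i] <- bad
    if (!bad) last_ok <- x
  }
  flagged
}

#' Spectral-estimation configuration
#'
#' Beat intervals are unevenly sampled in time; the default estimator
#' interpolates the tachogram with a cubic spline, resamples it evenly at
#' `fs_hz`, removes a linear trend, and averages Hann-windowed,
#' 50%-overlapped Welch segments of `nperseg` samples. A Lomb-Scargle
#' periodogram (which works on the uneven beat times directly) is
#' selectable for sensitivity checks.
#'
#' @param method `"welch"` or `"lombscargle"`.
#' @param fs_hz even-resampling rate (Hz) for the Welch path.
#' @param nperseg Welch segment length in samples (at `fs_hz`). The
#'   default, 180 samples = 45 s, gives a 0.022-Hz frequency step: fine
#'   enough that a Hann-windowed peak anywhere in the LF band stays
#'   inside the band.
#' @param detrend remove a linear trend before windowing.
#' @param min_duration_s minimum recording span (s); shorter recordings
#'   are an error because the LF band needs several 25-s cycles.
#' @return A `spectral_config` list.
#' @export
spectral_config <- function(method = c("welch", "lombscargle"), fs_hz = 4,
                            nperseg = 180, detrend = TRUE, min_duration_s = 60) {
  method <- match.arg(method)
  stopifnot(fs_hz > 0.8, nperseg >= 16, min_duration_s > 0)
  structure(list(method = method, fs_hz = fs_hz, nperseg = nperseg,
                 detrend = detrend, min_duration_s = min_duration_s),
            class = "spectral_config")
}

#' Estimate the power spectral density of an RR-interval series
#'
#' @param intervals numeric beat intervals (ms), assumed QC-accepted.
#' @param cfg a [spectral_config()].
#' @return A tibble with columns `freq_hz` and `density` (ms^2/Hz) on a
#'   grid covering at least [0, 0.4] Hz; densities are nonnegative.
#' @examples
#' rri <- generate_rri(90, 800, lf_amp_ms = 30, hf_amp_ms = 0)
#' psd <- estimate_psd(rri)
#' band_power(psd, 0.04, 0.15) # close to 30^2/2 = 450 ms^2
#' @export
estimate_psd <- function(intervals, cfg = spectral_config()) {
  if (length(intervals) < 4) stop_("too few beats for spectral analysis")
  span <- sum(intervals) / 1000
  if (span < cfg$min_duration_s)
    stop_("recording spans %.1f s, shorter than the configured minimum %.1f s",
          span, cfg$min_duration_s)
  res <- if (cfg$method == "welch") welch_psd(intervals, cfg) else lomb_psd(intervals, cfg)
  tibble(freq_hz = res$freq_hz, density = res$density)
}

welch_psd <- function(intervals, cfg) {
  beat_t <- cumsum(intervals) / 1000
  grid <- seq(beat_t[1], beat_t[length(beat_t)], by = 1 / cfg$fs_hz)
  x <- spline(beat_t, intervals, xout = grid)$y
  if (cfg$detrend) {
    tt <- seq_along(x)
    b <- stats::cov(tt, x) / stats::var(tt)
    x <- x - (mean(x) + b * (tt - mean(tt)))
  }
  n <- length(x)
  nseg <- min(cfg$nperseg, n)
  step <- max(1L, floor(nseg / 2))
  starts <- seq(1L, n - nseg + 1L, by = step)
  k <- seq_len(nseg) - 1L
  w <- 0.5 * (1 - cos(2 * pi * k / (nseg - 1)))   # Hann
  u <- sum(w^2)
  half <- floor(nseg / 2) + 1L
  acc <- numeric(half)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    xf <- fft(seg)
    acc <- acc + (Mod(xf[seq_len(half)])^2)
  }
  p <- acc / length(starts) * 2 / (cfg$fs_hz * u)  # one-sided density
  p[1] <- p[1] / 2
  if (nseg %% 2 == 0) p[half] <- p[half] / 2
  list(freq_hz = (seq_len(half) - 1L) * cfg$fs_hz / nseg, density = p)
}

# Classic Lomb-Scargle periodogram on the uneven beat times, rescaled so
# the density integrates to the series variance over the evaluable grid
# (Parseval convention); adequate for band-power comparisons, not for
# absolute narrow-band amplitudes. The grid stops at the mean beat-rate
# Nyquist so aliased images do not absorb normalised power.
lomb_psd <- function(intervals, cfg) {
  beat_t <- cumsum(intervals) / 1000
  x <- intervals - mean(intervals)
  f_max <- min(cfg$fs_hz / 2, 500 / mean(intervals))
  df <- 1 / (beat_t[length(beat_t)] - beat_t[1]) / 2   # 2x oversampled grid
  freqs <- seq(df, f_max, by = df)
  pw <- vapply(freqs, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * beat_t)), sum(cos(2 * w * beat_t))) / (2 * w)
    ct <- cos(w * (beat_t - tau)); st <- sin(w * (beat_t - tau))
    0.5 * (sum(x * ct)^2 / sum(ct^2) + sum(x * st)^2 / sum(st^2))
  }, numeric(1))
  total <- sum((head(pw, -1) + tail(pw, -1)) / 2 * df)
  dens <- if (total > 0) pw * var(x) / total else pw * 0
  list(freq_hz = c(0, freqs), density = c(0, dens))
}

#' Integrate spectral density over a frequency band
#'
#' Trapezoidal integral of the density from `lo` to `hi`, with linear
#' interpolation at the band edges. Bands are treated as half-open
#' `[lo, hi)` so that contiguous bands share each edge exactly once and
#' LF + HF equals the integral over the combined band.
#'
#' @param psd tibble from [estimate_psd()] (`freq_hz`, `density`).
#' @param lo,hi band edges in Hz, `lo < hi`, inside the PSD grid.
#' @return Band power in ms^2.
#' @export
band_power <- function(psd, lo, hi) {
  if (hi <= lo) stop_("inverted or empty band: [%g, %g)", lo, hi)
  band_power_(psd$freq_hz, psd$density, lo, hi)
}

band_power_ <- function(f, p, lo, hi) {
  if (lo < min(f) - 1e-12 || hi > max(f) + 1e-12)
    stop_("band [%g, %g) outside the PSD grid [%g, %g]", lo, hi, min(f), max(f))
  inside <- f > lo & f < hi
  xs <- c(lo, f[inside], hi)
  ys <- approx(f, p, xout = xs, rule = 2)$y
  sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)
}

#' Frequency bands for the autonomic indices
#'
#' LF (sympathetic-dominated) 0.04-0.15 Hz; HF (parasympathetic,
#' respiratory) 0.15-0.4 Hz. Half-open on the right.
#' @export
hrv_bands <- function() list(lf = c(0.04, 0.15), hf = c(0.15, 0.40))

#' Summarise one RR-interval recording
#'
#' Runs QC, spectral estimation, band integration, and the LF deviation
#' score for a single recording. Rejected recordings get `NA` spectral
#' fields: they are excluded from all downstream statistics.
#'
#' @param intervals beat intervals in ms.
#' @param age driver age (years), for the LF score; `NA` skips the score.
#' @param norms a `norm_table` (default [default_norm_table()]).
#' @param cfg a [spectral_config()].
#' @param policy a [qc_policy()].
#' @return One-row tibble: `n_beats`, `accepted`, `lf_power`, `hf_power`,
#'   `lf_hf`, `rri_average`, `lf_score`.
#' @export
hrv_summary <- function(intervals, age = NA_real_, norms = default_norm_table(),
                        cfg = spectral_config(), policy = qc_policy()) {
  v <- hrv_summary_(intervals, cfg, policy)
  score <- NA_real_
  if (v[["accepted"]] == 1 && !is.na(age) && is.finite(v[["lf_power"]]) && v[["lf_power"]] > 0)
    score <- lf_score(v[["lf_power"]], v[["rri_average"]], age, norms)
  tibble(n_beats = as.integer(v[["n_beats"]]), accepted = v[["accepted"]] == 1,
         lf_power = v[["lf_power"]], hf_power = v[["hf_power"]],
         lf_hf = v[["lf_hf"]], rri_average = v[["rri_average"]],
         lf_score = score)
}

# numeric-vector fast path shared by hrv_summary and summarize_hrv
hrv_summary_ <- function(intervals, cfg, policy) {
  flagged <- qc_flags(intervals, policy)
  ok <- mean(flagged) <= policy$max_flagged_fraction
  out <- c(n_beats = length(intervals), accepted = as.numeric(ok),
           lf_power = NA_real_, hf_power = NA_real_, lf_hf = NA_real_,
           rri_average = NA_real_)
  if (!ok) return(out)
  span <- sum(intervals) / 1000
  if (span < cfg$min_duration_s)
    stop_("recording spans %.1f s, shorter than the configured minimum %.1f s",
          span, cfg$min_duration_s)
  psd <- if (cfg$method == "welch") welch_psd(intervals, cfg) else lomb_psd(intervals, cfg)
  bands <- hrv_bands()
  lf <- band_power_(psd$freq_hz, psd$density, bands$lf[1], bands$lf[2])
  hf <- band_power_(psd$freq_hz, psd$density, bands$hf[1], bands$hf[2])
  out[["lf_power"]] <- lf
  out[["hf_power"]] <- hf
  out[["lf_hf"]] <- if (hf > 0) lf / hf else NA_real_
  out[["rri_average"]] <- mean(intervals)
  out
}

#' Summarise every recording of a cohort
#'
#' @param recordings tibble with columns `driver_id`, `date`, `condition`
#'   and a list-column `intervals` of numeric beat-interval vectors (the
#'   nested form produced by [generate_cohort()]; see [rri_from_long()]
#'   to build it from a long `rri.csv` table).
#' @param drivers tibble with `driver_id` and `age`.
#' @inheritParams hrv_summary
#' @return Tibble with one row per recording: keys plus the
#'   [hrv_summary()] columns.
#' @export
summarize_hrv <- function(recordings, drivers, norms = default_norm_table(),
                          cfg = spectral_config(), policy = qc_policy()) {
  stopifnot(all(c("driver_id", "date", "condition", "intervals") %in% names(recordings)))
  rec <- left_join(recordings, select(drivers, "driver_id", "age"), by = "driver_id")
  m <- vapply(rec$intervals, hrv_summary_, numeric(6), cfg = cfg, policy = policy)
  accepted <- m["accepted", ] == 1
  score <- rep(NA_real_, ncol(m))
  can <- accepted & !is.na(rec$age) & is.finite(m["lf_power", ]) & m["lf_power", ] > 0
  if (any(can))
    score[can] <- lf_score(m["lf_power", can], m["rri_average", can],
                           rec$age[can], norms)
  dplyr::bind_cols(
    select(rec, "driver_id", "date", "condition"),
    tibble(n_beats = as.integer(m["n_beats", ]), accepted = accepted,
           lf_power = m["lf_power", ], hf_power = m["hf_power", ],
           lf_hf = m["lf_hf", ], rri_average = m["rri_average", ],
           lf_score = score)
  )
}

#' Nest a long RRI table into per-recording interval vectors
#'
#' @param rri_long tibble with columns `driver_id`, `date`, `condition`,
#'   `beat_index`, `rri_ms` (the `rri.csv` dialect).
#' @return Tibble with one row per recording and a list-column `intervals`.
#' @export
rri_from_long <- function(rri_long) {
  rri_long %>%
    arrange(.data$driver_id, .data$date, .data$condition, .data$beat_index) %>%
    group_by(.data$driver_id, .data$date, .data$condition) %>%
    summarise(intervals = list(.data$rri_ms), .groups = "drop")
}
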