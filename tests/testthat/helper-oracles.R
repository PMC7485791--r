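# Independent spectral oracle: linear-interpolation resampling and a
# plain full-length rectangular-window periodogram, with band power as a
# bin sum. Shares no code path with the package's spline + Welch + Hann
# estimator; used to cross-check band powers on synthetic sinusoids.
oracle_band_power <- function(intervals, lo, hi, fs = 4) {
  beat_t <- cumsum(intervals) / 1000
  grid <- seq(beat_t[1], beat_t[length(beat_t)], by = 1 / fs)
  x <- approx(beat_t, intervals, xout = grid)$y
  x <- x - mean(x)
  n <- length(x)
  spec <- Mod(fft(x))^2 / n^2          # two-sided power per bin
  freqs <- (seq_len(n) - 1) * fs / n
  half <- freqs <= fs / 2
  pow <- 2 * spec                      # fold negative frequencies
  sum(pow[half & freqs >= lo & freqs < hi])
}

# reference rule set written out independently of rule_classify()
oracle_rules <- function(duration, speed_deviation, max_speed) {
  as.integer((duration > 79.0 & speed_deviation > 5.8 & speed_deviation <= 6.5 &
                max_speed > 39) |
               (duration > 42.5 & max_speed < 39))
}

# minimal feature row for rule tests
feat_row <- function(duration, max_speed, speed_deviation,
                     min_speed = 10, avg_speed = (min_speed + max_speed) / 2,
                     max_decel_per_s = 1) {
  tibble::tibble(duration = duration, max_speed = max_speed,
                 min_speed = min_speed, avg_speed = avg_speed,
                 speed_deviation = speed_deviation,
                 max_decel_per_s = max_decel_per_s)
}
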