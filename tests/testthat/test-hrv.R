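test_that("clean series passes QC and the flagged fraction drives rejection", {
  clean <- qc_rri(rep(800, 112))
  expect_equal(clean$n_flagged, 0)
  expect_true(clean$accepted)

  # 15 of 100 beats outside the physiological range
  bad <- c(rep(800, 85), rep(2500, 15))
  rep15 <- qc_rri(bad)
  expect_equal(rep15$flagged_fraction, 0.15)
  expect_false(rep15$accepted)

  # boundary: exactly 10% flagged is accepted, 11% rejected
  r10 <- qc_rri(c(rep(800, 90), rep(2500, 10)))
  expect_true(r10$accepted)
  r11 <- qc_rri(c(rep(800, 89), rep(2500, 11)))
  expect_false(r11$accepted)

  expect_error(qc_rri(numeric(0)), "empty")
})

test_that("QC decision depends only on the flagged fraction, not beat positions", {
  base <- rep(800, 100)
  for (seed in 1:5) {
    pos <- withr::with_seed(seed, sample(2:100, 10))  # avoid index 1 edge case
    x <- base
    x[pos] <- 250
    r <- qc_rri(x)
    expect_equal(r$n_flagged, 10)
    expect_true(r$accepted)
  }
})

test_that("jump flags use the previous accepted interval as reference", {
  # 800 -> 1000 is a 25% jump (flag), 1000 -> 1000 compares against the
  # last accepted 800, still >20% off, so it stays flagged
  r <- qc_rri(c(rep(800, 8), 1000, 1000))
  expect_equal(r$n_flagged, 2)
})

test_that("constant series has essentially no power above 0.04 Hz", {
  psd <- estimate_psd(rep(800, 120))
  hi <- psd$density[psd$freq_hz >= 0.04]
  expect_true(all(hi >= 0))
  expect_lt(band_power(psd, 0.04, 0.4), 1e-6)
})

test_that("band powers of pure sinusoidal modulation match A^2/2 and an independent periodogram", {
  rri_lf <- generate_rri(90, 800, lf_amp_ms = 30, hf_amp_ms = 0)
  psd <- estimate_psd(rri_lf)
  lf <- band_power(psd, 0.04, 0.15)
  hf <- band_power(psd, 0.15, 0.40)
  expect_equal(lf, 450, tolerance = 0.10)
  expect_lt(hf, 0.05 * 450)
  expect_equal(lf, oracle_band_power(rri_lf, 0.04, 0.15), tolerance = 0.10)

  rri_hf <- generate_rri(90, 800, lf_amp_ms = 0, hf_amp_ms = 20)
  psd_hf <- estimate_psd(rri_hf)
  expect_equal(band_power(psd_hf, 0.15, 0.40), 200, tolerance = 0.10)
  expect_lt(band_power(psd_hf, 0.04, 0.15), 0.05 * 200)

  # two-component series: each band integral tracks its own component
  rri2 <- generate_rri(90, 800, lf_amp_ms = 30, hf_amp_ms = 20,
                       lf_freq_hz = 0.10, hf_freq_hz = 0.30)
  psd2 <- estimate_psd(rri2)
  expect_equal(band_power(psd2, 0.04, 0.15), 450, tolerance = 0.10)
  expect_equal(band_power(psd2, 0.15, 0.40), 200, tolerance = 0.10)
  expect_equal(band_power(psd2, 0.04, 0.15),
               oracle_band_power(rri2, 0.04, 0.15), tolerance = 0.10)
})

test_that("Lomb-Scargle alternative agrees with Welch on sinusoidal band powers", {
  rri <- generate_rri(90, 800, lf_amp_ms = 30, hf_amp_ms = 20)
  psd_ls <- estimate_psd(rri, spectral_config(method = "lombscargle"))
  expect_equal(band_power(psd_ls, 0.04, 0.15), 450, tolerance = 0.15)
  expect_equal(band_power(psd_ls, 0.15, 0.40), 200, tolerance = 0.15)
})

test_that("estimate_psd rejects too-short recordings", {
  expect_error(estimate_psd(rep(800, 30)), "shorter")
})

test_that("band_power integrates exactly on analytic densities", {
  flat <- tibble::tibble(freq_hz = seq(0, 0.5, by = 0.01),
                         density = rep(1, 51))
  expect_equal(band_power(flat, 0.04, 0.15), 0.11)
  expect_equal(band_power(flat, 0.15, 0.40), 0.25)
  zero <- tibble::tibble(freq_hz = seq(0, 0.5, by = 0.01), density = rep(0, 51))
  expect_equal(band_power(zero, 0.04, 0.15), 0)
  expect_error(band_power(flat, 0.15, 0.04), "inverted")
  expect_error(band_power(flat, 0.4, 0.9), "outside")
})

test_that("contiguous bands are additive: LF + HF equals the combined integral", {
  rri <- generate_rri(90, 800, lf_amp_ms = 25, hf_amp_ms = 15, noise_sd_ms = 10,
                      seed = 3)
  psd <- estimate_psd(rri)
  expect_equal(band_power(psd, 0.04, 0.15) + band_power(psd, 0.15, 0.40),
               band_power(psd, 0.04, 0.40), tolerance = 1e-10)
})

test_that("LF deviation score is the documented affine transform of ln(LF/RRI)", {
  nt <- default_norm_table()
  ns <- fatiguerisk:::norm_lookup(nt, 45)
  at <- function(x) exp(x) * 800  # LF power giving ln(LF/RRI) = x at RRI 800
  expect_equal(lf_score(at(ns$mu), 800, 45, nt), 50)
  for (k in c(-2, -1, 1, 2))
    expect_equal(lf_score(at(ns$mu + k * ns$sigma), 800, 45, nt), 50 + 10 * k)

  # hand computation: x = mu + 1 with sigma = 2 gives 10*(1)/2 + 50 = 55
  nt2 <- fatiguerisk:::validate_norm_table(
    tibble::tibble(age_lo = 20, age_hi = 70, mu_lf = -0.5, sigma_lf = 2))
  expect_equal(lf_score(exp(-0.5 + 1) * 800, 800, 40, nt2), 55)

  expect_error(lf_score(0, 800, 45, nt), "lf_power")
  expect_error(lf_score(100, 800, 95, nt), "coverage")
})

test_that("LF score obeys the log-linear law and is monotone in LF power", {
  nt <- default_norm_table()
  base <- lf_score(300, 800, 52, nt)
  ns <- fatiguerisk:::norm_lookup(nt, 52)
  for (k in c(-1.5, -0.5, 0.5, 2))
    expect_equal(lf_score(300 * exp(k * ns$sigma), 800, 52, nt) - base, 10 * k)
  lfs <- lf_score(c(100, 200, 400, 800), 800, 30, nt)
  expect_true(all(diff(lfs) > 0))
})

test_that("LF/HF ratio behaves and guards its domain", {
  expect_equal(lf_hf(450, 450), 1.0)
  expect_equal(lf_hf(450, 200), 2.25)
  expect_equal(lf_hf(0, 200), 0)
  expect_error(lf_hf(450, 0), "undefined")
  # monotone: increasing in LF, decreasing in HF
  expect_true(lf_hf(500, 200) > lf_hf(450, 200))
  expect_true(lf_hf(450, 300) < lf_hf(450, 200))
})

test_that("hrv_summary withholds spectral fields for rejected recordings", {
  bad <- c(rep(800, 80), rep(2500, 20))
  s <- hrv_summary(bad, age = 45)
  expect_false(s$accepted)
  expect_true(is.na(s$lf_power) && is.na(s$lf_score))

  good <- generate_rri(90, 800, lf_amp_ms = 30, hf_amp_ms = 20)
  s2 <- hrv_summary(good, age = 45)
  expect_true(s2$accepted)
  expect_equal(s2$lf_hf, s2$lf_power / s2$hf_power)
  expect_equal(s2$rri_average, mean(good))
})

test_that("norm table loader validates structure", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(default_norm_table(), path)
  nt <- read_norm_table(path)
  expect_s3_class(nt, "norm_table")
  bad <- default_norm_table()
  bad$sigma_lf[2] <- 0
  expect_error(fatiguerisk:::validate_norm_table(bad), "sigma_lf")
  gap <- default_norm_table()[c(1, 3), ]
  expect_error(fatiguerisk:::validate_norm_table(gap), "contiguous")
})
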