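test_that("constant-rate IPFM fires at exact one-second marks", {
  prof <- make_profile(mean_hr = 60, rsa_amp = 0, lf_amp = 0)
  bs <- generate_beat_series(prof, "1D", 60, seed = 1, hrv_noise = 0)
  # beat at t = 0 plus one per integer threshold: 61 beats over [0, 60]
  expect_length(bs$beat_times, 61)
  expect_equal(bs$beat_times, 0:60, tolerance = 1e-6)
})

test_that("beat generation is seed-deterministic and seed-sensitive", {
  prof <- make_profile(rsa_amp = 0.05)
  a <- generate_beat_series(prof, "1D", 60, seed = 5, hrv_noise = 0.02)
  b <- generate_beat_series(prof, "1D", 60, seed = 5, hrv_noise = 0.02)
  c <- generate_beat_series(prof, "1D", 60, seed = 6, hrv_noise = 0.02)
  expect_identical(a$beat_times, b$beat_times)
  expect_false(identical(a$beat_times, c$beat_times))
})

test_that("RSA modulation dominates the interval-series spectrum", {
  prof <- make_profile(rsa_amp = 0.1, lf_amp = 0, resp_rate = 0.25)
  bs <- generate_beat_series(prof, "1D", 300, seed = 2, hrv_noise = 0)
  # independent oracle: raw periodogram of the spline-resampled inverse
  # interval series (stats::spec.pgram, not the package's Welch code)
  nn <- diff(bs$beat_times)
  mid <- (bs$beat_times[-1] + bs$beat_times[-length(bs$beat_times)]) / 2
  x <- stats::spline(mid, 1 / nn, xout = seq(5, 295, by = 0.25))$y
  sp <- stats::spec.pgram(stats::ts(x - mean(x), frequency = 4), plot = FALSE,
                          taper = 0, detrend = TRUE)
  expect_lt(abs(sp$freq[which.max(sp$spec)] - 0.25), 0.01)
})

test_that("zero modulation and zero noise give identical QRS complexes", {
  prof <- make_profile(mean_hr = 60, rsa_amp = 0, lf_amp = 0)
  bs <- generate_beat_series(prof, "1D", 30, seed = 1, hrv_noise = 0)
  fs <- 500
  tt <- seq(0, 30, by = 1 / fs)
  ecg <- generate_ecg(bs$beat_times, numeric(length(tt)),
                      morph = qrs_morphology(mod_depth = 0.05), fs = fs,
                      duration = 30)
  # beats on integer seconds -> identical sample alignment
  w <- round(0.04 * fs)
  windows <- vapply(2:29, function(k) {
    i <- k * fs + 1
    ecg$leads[(i - w):(i + w), 1]
  }, numeric(2 * w + 1))
  expect_lt(max(apply(windows, 1, function(r) diff(range(r)))), 1e-12)
})

test_that("respiratory modulation appears in the beat-indexed slope series", {
  fx <- make_ecg_fixture(rate = 0.3, fs = 1000, duration = 120, mod_depth = 0.05)
  rec <- remove_baseline(fx$ecg)
  beats <- detect_beats(rec$leads[, 2], fx$fs)
  edr <- edr_signals(rec, beats)
  ss <- edr$slope_series[[2]]
  base <- cbind(sin(2 * pi * 0.3 * ss$beat_time), cos(2 * pi * 0.3 * ss$beat_time))
  y <- ss$i_us - mean(ss$i_us)
  fit <- stats::lm.fit(base, y)
  r2 <- 1 - sum(fit$residuals^2) / sum(y^2)
  expect_gt(r2, 0.9)
})

test_that("overlapping QRS templates are rejected", {
  expect_error(
    generate_ecg(c(0.5, 0.55), numeric(1001), fs = 1000, duration = 1),
    "overlapping"
  )
})

test_that("baseline drift injected by the generator is recoverable", {
  prof <- make_profile(mean_hr = 60, rsa_amp = 0, lf_amp = 0)
  bs <- generate_beat_series(prof, "1D", 200, seed = 1, hrv_noise = 0)
  fs <- 250
  tt <- seq(0, 200, by = 1 / fs)
  m0 <- qrs_morphology(mod_depth = 0)
  m1 <- qrs_morphology(mod_depth = 0, drift_amp = 0.2, drift_freq = 0.01)
  e0 <- generate_ecg(bs$beat_times, numeric(length(tt)), morph = m0, fs = fs,
                     seed = 9, duration = 200)
  e1 <- generate_ecg(bs$beat_times, numeric(length(tt)), morph = m1, fs = fs,
                     seed = 9, duration = 200)
  drift <- e1$leads[, 1] - e0$leads[, 1]
  est <- lowpass_trend(e1$leads[, 1], fs, 0.03)
  interior <- tt > 40 & tt < 160
  rel_rmse <- sqrt(mean((est[interior] - drift[interior])^2)) /
    sqrt(mean(drift[interior]^2))
  expect_lt(rel_rmse, 0.05)
})

test_that("cohort generation flags the requested anomalous subjects", {
  coh <- generate_cohort(8, 2, config = cohort_config(stage_duration = 60),
                         seed = 3)
  expect_length(coh$subjects, 8)
  expect_length(anomalous_ids(coh), 2)
  coh0 <- generate_cohort(4, 0, config = cohort_config(stage_duration = 60),
                          seed = 3)
  expect_length(anomalous_ids(coh0), 0)
  coh2 <- generate_cohort(8, 2, config = cohort_config(stage_duration = 60),
                          seed = 4)
  bt1 <- coh$subjects[[1]]$records[["1D"]]$truth$beat_times
  bt2 <- coh2$subjects[[1]]$records[["1D"]]$truth$beat_times
  expect_false(identical(bt1, bt2))
  expect_error(generate_cohort(4, 4), "n_anomalous")
})

test_that("HRV extracted from generated beats recovers the modulating signal", {
  prof <- make_profile(rsa_amp = 0.08, lf_amp = 0.03, resp_rate = 0.25)
  bs <- generate_beat_series(prof, "1D", 300, seed = 4, hrv_noise = 0)
  hr <- instantaneous_hr(bs$beat_times, t_out = bs$t)
  sh <- split_hrv(hr)
  expect_gt(stats::cor(sh$hrv, bs$m * mean(hr$hr)), 0.9)
})

test_that("generated respiratory rate matches the configured value spectrally", {
  prof <- make_profile(resp_rate = 0.22)
  rec <- generate_stage_record(prof, "1D", duration = 120, seed = 5,
                               level = "beats", hrv_noise = 0)
  s <- welch_psd(rec$truth$resp4, 4)
  expect_lt(abs(s$f[which.max(s$psd)] - 0.22), 0.01)
  expect_equal(unique(rec$truth$resp_rate_track$f), 0.22)
})
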