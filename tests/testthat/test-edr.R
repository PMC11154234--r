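test_that("least-squares slope recovers an exact linear flank", {
  fs <- 1000
  lead <- 0.8 * (seq_len(100) - 1) / fs * 1000  # 0.8 mV/ms ramp
  sl <- fit_slopes(lead, fs, n_u = 0.05, n_d = 0.05)
  expect_equal(sl$i_us, 0.8, tolerance = 1e-12)
  flat <- fit_slopes(rep(2, 100), fs, n_u = 0.05, n_d = 0.05)
  expect_equal(flat$i_us, 0, tolerance = 1e-12)
})

test_that("slope under noise equals the closed-form least-squares solution", {
  fs <- 2000
  set.seed(13)
  n <- 200
  t_ms <- (seq_len(n) - 1) / fs * 1000
  lead <- 0.1 + 1.3 * t_ms + stats::rnorm(n, 0, 0.01)
  centre <- 0.03
  sl <- fit_slopes(lead, fs, n_u = centre, n_d = centre)
  # independent oracle: stats::lm on the same window
  half <- round(0.004 * fs)
  idx <- (round(centre * fs) + 1 - half):(round(centre * fs) + 1 + half)
  oracle <- unname(stats::coef(stats::lm(lead[idx] ~ t_ms[idx]))[2])
  expect_equal(sl$i_us, oracle, tolerance = 1e-10)
})

test_that("the R-wave angle formula matches its printed special cases", {
  expect_equal(rwave_angle(2, 2), 0)
  expect_equal(rwave_angle(2.5, -2.5), pi / 2)
  expect_equal(rwave_angle(3, -1), atan(4 / (0.4 * 3.25)))
})

test_that("the angle equals the geometric angle between the scaled lines", {
  set.seed(99)
  for (i in 1:200) {
    a <- stats::runif(1, -6, 6)
    b <- stats::runif(1, -6, 6)
    # geometric oracle: difference of the two line angles after scaling the
    # time axis by 2.5, folded into (-pi/2, pi/2]
    d <- atan(a / 2.5) - atan(b / 2.5)
    if (d > pi / 2) d <- d - pi
    if (d <= -pi / 2) d <- d + pi
    expect_equal(rwave_angle(a, b), d, tolerance = 1e-9)
  }
})

test_that("maximum-variation points sit at the steepest template samples", {
  # cosine-ramp template: unique steepest point mid-flank
  fs <- 1000
  morph <- qrs_morphology()
  tt <- seq(-0.06, 0.07, by = 1 / fs)
  lead <- hyperhrv:::qrs_template_eval(tt * 1000,
                                       hyperhrv:::qrs_template_knots(morph))
  r_i <- which.max(lead)
  beats <- hyperhrv:::new_beat_annotations(
    r_times = (r_i - 1) / fs,
    q_times = (which.min(lead[1:r_i]) - 1) / fs,
    s_times = (r_i + which.min(lead[r_i:length(lead)]) - 2) / fs)
  sp <- locate_slope_points(lead, fs, beats)
  # steepest up-slope: midpoint of the Q->R cosine ramp (rise 14 ms)
  t_mid_up <- (r_i - 1) / fs - morph$rise_ms / 2 / 1000
  t_mid_dn <- (r_i - 1) / fs + morph$fall_ms / 2 / 1000
  expect_lt(abs(sp$n_u - t_mid_up), 2.5 / fs)
  expect_lt(abs(sp$n_d - t_mid_dn), 2.5 / fs)
})

test_that("tied derivative maxima resolve to the earliest sample", {
  fs <- 1000
  # linear rise with exactly representable increments: the derivative is
  # constant on the flank, so the argmax is a genuine tie
  lead <- c(rep(0, 10), 0.25, 0.5, 0.75, 1, 1, 0.5, 0, rep(-0.2, 10))
  beats <- hyperhrv:::new_beat_annotations(r_times = 13 / fs,
                                           q_times = 9 / fs,
                                           s_times = 17 / fs)
  sp <- locate_slope_points(lead, fs, beats)
  expect_equal(round(sp$n_u * fs), 10)  # earliest of the four tied samples
  expect_equal(round(sp$n_d * fs), 15)  # earliest of the two tied down-slopes
})

test_that("EDR conditioning removes DC, keeps the modulation line, and
           is robust to one gross outlier", {
  set.seed(5)
  bt <- cumsum(stats::runif(300, 0.5, 0.7))
  vals <- 2 + 0.3 * sin(2 * pi * 0.2 * bt)
  e <- build_edr_signal(vals, bt)
  s <- welch_psd(e$x[e$t > 10 & e$t < max(bt) - 10], 4)
  expect_lt(abs(s$f[which.max(s$psd)] - 0.2), 0.01)
  const <- build_edr_signal(rep(3, 300), bt)
  expect_lt(max(abs(const$x)), 1e-8)
  vals_out <- vals
  vals_out[150] <- vals[150] + 10 * stats::mad(vals)
  e_out <- build_edr_signal(vals_out, bt)
  expect_equal(e_out$rejected, 1)
  rel <- sqrt(mean((e_out$x - e$x)^2)) / sqrt(mean(e$x^2))
  expect_lt(rel, 0.01)
  expect_error(build_edr_signal(1:5, 1:5), "at least 10")
})

test_that("a 3-lead record yields nine band-limited EDR signals peaking at
           the modulation frequency", {
  fx <- make_ecg_fixture(rate = 0.3, fs = 1000, duration = 120,
                         mod_depth = 0.05, hrv_noise = 0.01)
  rec <- remove_baseline(fx$ecg)
  beats <- detect_beats(rec$leads[, 2], fx$fs)
  edr <- edr_signals(rec, beats)
  expect_equal(ncol(edr$x), 9)
  expect_equal(sort(unique(edr$lead)), 1:3)
  expect_setequal(unique(edr$kind), c("Us", "Ds", "Ra"))
  sel <- edr$t > 10 & edr$t < 110
  for (j in 1:9) {
    s <- welch_psd(edr$x[sel, j], 4)
    expect_lt(abs(s$f[which.max(s$psd)] - 0.3), 0.01)
  }
})
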