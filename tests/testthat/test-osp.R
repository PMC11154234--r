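test_that("the delayed-respiration subspace has the expected structure", {
  set.seed(41)
  t <- seq(0, 239.75, by = 0.25)
  resp <- sin(2 * pi * 0.3 * t)
  V0 <- build_resp_subspace(resp, max_delay = 0)
  expect_equal(ncol(V0), 1)
  V <- build_resp_subspace(resp, max_delay = 40)
  expect_equal(ncol(V), 41)
  expect_equal(qr(V)$rank, 2)  # delayed sinusoids span sin and cos only
  noise <- stats::rnorm(length(t))
  Vn <- build_resp_subspace(noise, max_delay = 40)
  expect_equal(qr(Vn)$rank, 41)
  expect_error(build_resp_subspace(rep(1, 960)), "constant")
  V2 <- build_resp_subspace(resp, max_delay = 8, two_sided = TRUE)
  expect_equal(ncol(V2), 17)
})

test_that("in-span HRV projects entirely onto the respiratory component", {
  t <- seq(0, 239.75, by = 0.25)
  resp <- sin(2 * pi * 0.3 * t) + 0.3 * sin(2 * pi * 0.22 * t)
  V <- build_resp_subspace(resp, max_delay = 40)
  hrv <- 3 * c(rep(0, 2), resp[1:(length(resp) - 2)])  # resp delayed 2 samples
  fit <- osp_decompose(hrv, V)
  p <- component_powers(fit)
  expect_gt(p$p_r, 0.999)
  expect_lt(sqrt(mean(fit$hrv_perp^2)) / sqrt(mean(fit$hrv^2)), 0.05)
})

test_that("inputs orthogonal to the subspace stay in the residual", {
  set.seed(42)
  t <- seq(0, 239.75, by = 0.25)
  resp <- sin(2 * pi * 0.3 * t)
  V <- build_resp_subspace(resp, max_delay = 20)
  # construct an input orthogonal to every column by Gram-Schmidt
  x <- stats::rnorm(nrow(V))
  x <- x - mean(x)
  qv <- qr.Q(qr(V))
  x_perp <- x - qv %*% crossprod(qv, x)
  fit <- osp_decompose(as.numeric(x_perp), structure(V, rows = NULL,
                                                     delays = 0:20))
  expect_lt(mean(fit$hrv_r^2) / mean(fit$hrv^2), 1e-12)
})

test_that("the projection is idempotent and exactly additive", {
  set.seed(43)
  t <- seq(0, 239.75, by = 0.25)
  resp <- sin(2 * pi * 0.25 * t) + 0.2 * stats::rnorm(length(t))
  V <- build_resp_subspace(resp, max_delay = 40)
  hrv <- stats::rnorm(nrow(V))
  fit <- osp_decompose(hrv, structure(V, rows = NULL, delays = 0:40))
  # additivity is exact by construction
  expect_equal(fit$hrv_r + fit$hrv_perp, fit$hrv, tolerance = 1e-12)
  # orthogonality within 1e-8 relative
  expect_lt(abs(sum(fit$hrv_r * fit$hrv_perp)) /
              (sqrt(sum(fit$hrv_r^2)) * sqrt(sum(fit$hrv_perp^2)) + 1e-30),
            1e-8)
  # projecting the projection changes nothing
  fit2 <- osp_decompose(fit$hrv_r, structure(V, rows = NULL, delays = 0:40))
  expect_equal(fit2$hrv_r, fit$hrv_r - mean(fit$hrv_r), tolerance = 1e-10)
  # Pythagoras and the relative-power identity
  p <- component_powers(fit)
  expect_equal(p$p_r + p$p_perp, 1, tolerance = 1e-8)
})

test_that("residual band powers capture a line at the right band", {
  t <- seq(0, 239.75, by = 0.25)
  resp <- sin(2 * pi * 0.3 * t)
  V <- build_resp_subspace(resp, max_delay = 40)
  rows <- attr(V, "rows")
  lf_line <- sin(2 * pi * 0.1 * t)[rows]
  fit <- osp_decompose(as.numeric(lf_line), structure(V, rows = NULL,
                                                      delays = 0:40))
  p <- component_powers(fit)
  expect_gt(p$p_lf_perp / (p$p_lf_perp + p$p_hf_perp), 0.95)
  # degenerate zero-power input is flagged
  z <- component_powers(osp_decompose(numeric(nrow(V)),
                                      structure(V, rows = NULL, delays = 0:40)))
  expect_false(z$defined)
})

test_that("respiratory power rises with injected RSA depth across stages", {
  rsa <- c(`1D` = 0.01, `3D` = 0.02, `5` = 0.035, `3A` = 0.05, `1A` = 0.065)
  sp <- lapply(names(rsa), function(s) {
    list(mean_hr = 70, rsa_amp = unname(rsa[s]), lf_amp = 0.02,
         resp_rate = 0.3, resp_rate_drift = 0, noise_sd = 0)
  })
  names(sp) <- names(rsa)
  prof <- subject_profile(1, sp)
  p_r <- vapply(names(rsa), function(s) {
    rec <- generate_stage_record(prof, s, duration = 300, seed = 17,
                                 level = "beats", hrv_noise = 0)
    stage_features(rec)$p_r
  }, numeric(1))
  expect_true(all(diff(p_r) > 0))
})

test_that("respiration at 0.45 Hz does not inflate the residual HF power", {
  prof <- make_profile(rsa_amp = 0.06, lf_amp = 0.01, resp_rate = 0.45)
  rec <- generate_stage_record(prof, "1D", duration = 300, seed = 18,
                               level = "beats", hrv_noise = 0)
  f <- stage_features(rec)
  # the 0.45 Hz RSA line lives in the respiratory component, not the
  # residual HF band, even though 0.45 Hz lies outside the classical HF band
  expect_gt(f$p_r, 0.5)
  expect_lt(f$p_hf_perp, 0.15)
})
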