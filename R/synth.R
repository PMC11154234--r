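#' @importFrom stats rnorm runif sd quantile median approx spline
NULL

#' Hyperbaric protocol stage labels
#'
#' The five 5-minute chamber stops: 1 atm and 3 atm during descent, the
#' 5 atm bottom stage, and 3 atm and 1 atm during ascent.
#' @export
hyperbaric_stages <- function() c("1D", "3D", "5", "3A", "1A")

#' Subject profile for the synthetic cohort
#'
#' Bundles the per-stage physiological parameters that drive the generator:
#' mean heart rate, respiratory sinus arrhythmia (RSA) and low-frequency
#' autonomic modulation depths, respiratory rate and its drift, and the
#' additive ECG noise level.
#'
#' @param subject_id integer identifier.
#' @param stage_params named list, one entry per stage in
#'   [hyperbaric_stages()], each a list with `mean_hr` (beats/min, in
#'   \[30, 180\]), `rsa_amp`, `lf_amp` (dimensionless modulation depths),
#'   `resp_rate` (Hz, in \[0.07, 1\]), `resp_rate_drift` (Hz/min) and
#'   `noise_sd` (mV).
#' @param anomalous logical flag marking a subject whose stage response
#'   opposes the cohort trend.
#' @return object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, stage_params, anomalous = FALSE) {
  stages <- hyperbaric_stages()
  if (!setequal(names(stage_params), stages)) {
    stop("stage_params must have exactly the five stages ", paste(stages, collapse = ", "))
  }
  for (s in stages) {
    p <- stage_params[[s]]
    if (p$resp_rate < 0.07 || p$resp_rate > 1) {
      stop("resp_rate must lie in [0.07, 1] Hz (stage ", s, ")")
    }
    if (p$mean_hr < 30 || p$mean_hr > 180) {
      stop("mean_hr must lie in [30, 180] beats/min (stage ", s, ")")
    }
  }
  structure(list(subject_id = as.integer(subject_id),
                 stage_params = stage_params[stages],
                 anomalous = isTRUE(anomalous)),
            class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat("Subject", x$subject_id, if (x$anomalous) "(anomalous)" else "", "\n")
  hr <- vapply(x$stage_params, function(p) p$mean_hr, numeric(1))
  rr <- vapply(x$stage_params, function(p) p$resp_rate, numeric(1))
  cat("  mean HR (bpm):  ", paste(sprintf("%s=%.1f", names(hr), hr), collapse = "  "), "\n")
  cat("  resp rate (Hz): ", paste(sprintf("%s=%.3f", names(rr), rr), collapse = "  "), "\n")
  invisible(x)
}

# instantaneous respiratory frequency (Hz) and phase for a stage
resp_phase <- function(t, resp_rate, drift_per_min = 0) {
  f <- resp_rate + drift_per_min * t / 60
  phase <- 2 * pi * (resp_rate * t + drift_per_min * t^2 / 120)
  list(f = f, phase = phase)
}

#' Generate a beat series from the IPFM model
#'
#' Integral pulse frequency modulation: beats fire when the integral of
#' `(1 + m(t)) * mean_hr / 60` crosses successive integer thresholds, with a
#' beat placed at t = 0 (threshold 0). The modulating signal is
#' `m(t) = rsa_amp * sin(resp phase) + lf_amp * sin(2 pi 0.1 t)` plus
#' optional band-limited noise. The final partial interval (integral between
#' the last threshold and the end of the record) never fires, so a constant
#' 60 beats/min profile over 60 s yields 61 beats at 0, 1, ..., 60 s when
#' the integral exactly reaches the last threshold, and beats at 0 ... 59 s
#' otherwise.
#'
#' @param profile a [subject_profile()].
#' @param stage stage label, one of [hyperbaric_stages()].
#' @param duration record length in seconds (> 10).
#' @param seed integer seed; fixed seed gives identical beats.
#' @param hrv_noise standard deviation of band-limited (0.03-0.5 Hz) noise
#'   added to m(t); 0 disables it.
#' @return list with `beat_times` (s), `t` (4 Hz grid, s), `m` (modulating
#'   signal on that grid) and `resp_freq` (instantaneous respiratory rate on
#'   the same grid, Hz).
#' @export
generate_beat_series <- function(profile, stage, duration, seed = 1L,
                                 hrv_noise = 0) {
  stopifnot(inherits(profile, "subject_profile"))
  if (duration <= 10) stop("duration must exceed 10 s")
  p <- profile$stage_params[[stage]]
  if (is.null(p)) stop("unknown stage ", stage)
  set.seed(seed)
  fs_int <- 250  # integration grid
  tt <- seq(0, duration, by = 1 / fs_int)
  rp <- resp_phase(tt, p$resp_rate, p$resp_rate_drift)
  m <- p$rsa_amp * sin(rp$phase) + p$lf_amp * sin(2 * pi * 0.1 * tt)
  if (hrv_noise > 0) {
    z <- rnorm(length(tt))
    z <- fft_filter(z, fs_int, low = 0.03, high = 0.5)
    m <- m + hrv_noise * z / sd(z)
  }
  rate <- pmax((1 + m) * p$mean_hr / 60, 1e-6)
  ci <- c(0, cumsum((rate[-1] + rate[-length(rate)]) / 2) / fs_int)
  n_beats <- floor(ci[length(ci)] + 1e-9)
  beat_times <- numeric(n_beats + 1L)
  beat_times[1L] <- 0
  if (n_beats >= 1L) {
    idx <- findInterval(seq_len(n_beats) - 1e-12, ci)
    for (k in seq_len(n_beats)) {
      i <- idx[k]
      # linear interpolation of the integer crossing
      beat_times[k + 1L] <- tt[i] + (k - ci[i]) / (ci[i + 1L] - ci[i]) * (tt[i + 1L] - tt[i])
    }
  }
  t4 <- seq(0, duration, by = 0.25)
  rp4 <- resp_phase(t4, p$resp_rate, p$resp_rate_drift)
  m4 <- approx(tt, m, xout = t4)$y
  list(beat_times = beat_times, t = t4, m = m4, resp_freq = rp4$f)
}

# QRS template: cosine-ramp knots relative to the R peak (times in ms).
# The steepest up-slope sits mid-way on the Q->R ramp, the steepest
# down-slope mid-way on the R->S ramp, both on near-linear stretches that
# comfortably contain an 8 ms least-squares fit window.
qrs_template_knots <- function(morph) {
  data.frame(
    t_ms = c(-morph$q_onset_ms, -morph$rise_ms, 0, morph$fall_ms, morph$s_offset_ms),
    v = c(0, morph$q_amp, morph$r_amp, morph$s_amp, 0)
  )
}

qrs_template_eval <- function(t_ms, knots) {
  v <- numeric(length(t_ms))
  for (seg in seq_len(nrow(knots) - 1L)) {
    t1 <- knots$t_ms[seg]; t2 <- knots$t_ms[seg + 1L]
    sel <- t_ms >= t1 & t_ms < t2
    if (!any(sel)) next
    u <- (t_ms[sel] - t1) / (t2 - t1)
    v[sel] <- knots$v[seg] + (knots$v[seg + 1L] - knots$v[seg]) * (0.5 - 0.5 * cos(pi * u))
  }
  v
}

#' Default QRS morphology parameters
#'
#' Amplitudes in mV, times in ms, per-lead gains, and the multiplicative
#' respiratory modulation depth applied to the QRS amplitudes (hence to the
#' R-wave slopes and angle).
#' @param mod_depth respiratory modulation depth of the QRS amplitudes.
#' @param noise_sd additive band-limited (1-40 Hz) noise, mV.
#' @param drift_amp baseline-wander amplitude, mV (sinusoid at `drift_freq`).
#' @param drift_freq baseline-wander frequency, Hz (< 0.03).
#' @export
qrs_morphology <- function(mod_depth = 0.05, noise_sd = 0, drift_amp = 0,
                           drift_freq = 0.015) {
  list(r_amp = 1.0, q_amp = -0.12, s_amp = -0.18,
       rise_ms = 14, fall_ms = 14, q_onset_ms = 40, s_offset_ms = 52,
       lead_gain = c(1.0, 0.85, 1.15),
       lead_mod = c(1.0, 0.9, 1.1),
       mod_depth = mod_depth, noise_sd = noise_sd,
       drift_amp = drift_amp, drift_freq = drift_freq)
}

#' Synthesise a 3-lead ECG from beat times and a respiration signal
#'
#' Places a cosine-ramp QRS template at every beat time and scales its Q, R
#' and S amplitudes by `1 + mod_depth * resp(beat time)`, so the R-wave
#' up-slope, down-slope and angle all carry the respiratory modulation.
#' Band-limited noise and optional sub-0.03 Hz baseline wander are added per
#' lead.
#'
#' @param beat_times beat occurrence times in seconds.
#' @param resp_signal respiration surrogate sampled at `fs` covering the
#'   record (dimensionless, roughly unit amplitude).
#' @param morph morphology parameters from [qrs_morphology()].
#' @param fs sampling frequency in Hz (>= 250).
#' @param seed integer seed for the noise.
#' @param duration record length in seconds; defaults to the span covered by
#'   `resp_signal`.
#' @return an [ecg_record()] with 3 leads.
#' @export
generate_ecg <- function(beat_times, resp_signal, morph = qrs_morphology(),
                         fs = 2000, seed = 1L, duration = NULL) {
  if (fs < 250) stop("fs must be at least 250 Hz")
  if (is.null(duration)) duration <- (length(resp_signal) - 1L) / fs
  span_ms <- morph$q_onset_ms + morph$s_offset_ms
  if (length(beat_times) > 1L && min(diff(beat_times)) * 1000 < span_ms) {
    stop("overlapping QRS templates: beat interval shorter than template width")
  }
  set.seed(seed)
  n <- round(duration * fs) + 1L
  tt <- (seq_len(n) - 1L) / fs
  knots0 <- qrs_template_knots(morph)
  leads <- matrix(0, nrow = n, ncol = 3L)
  resp_at_beat <- approx(tt, resp_signal[seq_len(n)], xout = beat_times, rule = 2)$y
  for (l in 1:3) {
    x <- numeric(n)
    for (i in seq_along(beat_times)) {
      g <- 1 + morph$mod_depth * morph$lead_mod[l] * resp_at_beat[i]
      k <- knots0
      k$v <- k$v * g * morph$lead_gain[l]
      i0 <- max(1L, ceiling((beat_times[i] - morph$q_onset_ms / 1000) * fs) + 1L)
      i1 <- min(n, floor((beat_times[i] + morph$s_offset_ms / 1000) * fs) + 1L)
      if (i1 <= i0) next
      rel_ms <- (tt[i0:i1] - beat_times[i]) * 1000
      x[i0:i1] <- x[i0:i1] + qrs_template_eval(rel_ms, k)
    }
    if (morph$noise_sd > 0) {
      z <- rnorm(n)
      z <- fft_filter(z, fs, low = 1, high = 40)
      x <- x + morph$noise_sd * z / sd(z)
    }
    if (morph$drift_amp > 0) {
      x <- x + morph$drift_amp * sin(2 * pi * morph$drift_freq * tt + runif(1, 0, 2 * pi))
    }
    leads[, l] <- x
  }
  ecg_record(leads, fs = fs,
             stage_annotations = data.frame(stage = NA_character_,
                                            t_start = 0, t_end = duration))
}

#' Generate one synthetic stage record with ground truth
#'
#' Runs the IPFM beat generator and (optionally) the ECG synthesiser for one
#' subject-stage, returning the record together with every ground-truth
#' quantity a downstream test needs.
#'
#' @inheritParams generate_beat_series
#' @param fs ECG sampling frequency (Hz), used when `level = "ecg"`.
#' @param level `"ecg"` builds the full 3-lead ECG; `"beats"` stops at beat
#'   times plus the 4 Hz respiration surrogate (fast path for cohort-scale
#'   studies of the feature/classification machinery).
#' @param morph morphology parameters, see [qrs_morphology()]; its
#'   `noise_sd` is overridden by the profile's stage value.
#' @return list with `ecg` (an [ecg_record()] or `NULL`), `truth` (beat
#'   times, 4 Hz respiration `resp4`, modulating signal `m`, respiratory
#'   rate track every 5 s), and `stage`.
#' @export
generate_stage_record <- function(profile, stage, duration = 300, fs = 2000,
                                  seed = 1L, level = c("ecg", "beats"),
                                  morph = qrs_morphology(), hrv_noise = 0.01) {
  level <- match.arg(level)
  p <- profile$stage_params[[stage]]
  bs <- generate_beat_series(profile, stage, duration, seed = seed,
                             hrv_noise = hrv_noise)
  resp4 <- sin(resp_phase(bs$t, p$resp_rate, p$resp_rate_drift)$phase)
  t5 <- seq(2.5, duration - 2.5, by = 5)
  track <- data.frame(t = t5,
                      f = resp_phase(t5, p$resp_rate, p$resp_rate_drift)$f)
  ecg <- NULL
  if (level == "ecg") {
    tt <- seq(0, duration, by = 1 / fs)
    resp_fs <- sin(resp_phase(tt, p$resp_rate, p$resp_rate_drift)$phase)
    morph$noise_sd <- p$noise_sd
    ecg <- generate_ecg(bs$beat_times, resp_fs, morph = morph, fs = fs,
                        seed = seed + 1L, duration = duration)
    ecg$stage_annotations <- data.frame(stage = stage, t_start = 0,
                                        t_end = duration)
    ecg$subject_id <- profile$subject_id
  }
  list(stage = stage, ecg = ecg,
       truth = list(beat_times = bs$beat_times, t4 = bs$t, resp4 = resp4,
                    m = bs$m, resp_rate_track = track,
                    resp_rate = p$resp_rate))
}

#' Cohort generator configuration
#'
#' Baseline parameter means and between-subject spreads, the normal
#' stage-effect template (multiplicative factors relative to stage 1D), and
#' the anomalous-response multipliers. Factors encode the cohort-level
#' directions reported for hyperbaric exposure: heart rate falls with
#' depth and stays low through ascent (so NN intervals lengthen, maximal at
#' 1A), vagally driven RSA rises with pressure (maximal at the bottom
#' stage), low-frequency (sympathetic-related) modulation rises during
#' descent and falls below baseline during ascent, and respiratory rate
#' creeps up through the protocol. Magnitudes are generator defaults, not
#' measured effect sizes.
#'
#' @param stage_duration seconds per stage.
#' @param fs ECG sampling rate (Hz) for `level = "ecg"` cohorts.
#' @return configuration list.
#' @export
cohort_config <- function(stage_duration = 300, fs = 2000) {
  list(
    stage_duration = stage_duration,
    fs = fs,
    base = list(mean_hr = 70, rsa_amp = 0.045, lf_amp = 0.030,
                resp_rate = 0.25, resp_rate_drift = 0, noise_sd = 0.03),
    base_sd = list(mean_hr = 6, rsa_amp = 0.22, lf_amp = 0.22,  # rsa/lf: log-normal sdlog
                   resp_rate = 0.03),
    stage_factors = list(
      `1D` = c(mean_hr = 1.00, rsa_amp = 1.00, lf_amp = 1.00, resp_rate = 1.00),
      `3D` = c(mean_hr = 0.96, rsa_amp = 1.20, lf_amp = 1.30, resp_rate = 1.03),
      `5`  = c(mean_hr = 0.93, rsa_amp = 1.50, lf_amp = 1.45, resp_rate = 1.05),
      `3A` = c(mean_hr = 0.92, rsa_amp = 1.40, lf_amp = 0.80, resp_rate = 1.09),
      `1A` = c(mean_hr = 0.90, rsa_amp = 1.30, lf_amp = 0.70, resp_rate = 1.12)
    ),
    factor_jitter_sd = 0.02,
    # anomalous subjects: deviation from baseline is scaled by these
    # multipliers (negative = response opposing the cohort trend)
    anomaly_mult = c(mean_hr = -0.5, rsa_amp = -1, lf_amp = -1, resp_rate = -1),
    hrv_noise = 0.02
  )
}

draw_profile <- function(subject_id, anomalous, config) {
  b <- config$base
  hr0 <- min(180, max(30, rnorm(1, b$mean_hr, config$base_sd$mean_hr)))
  rsa0 <- b$rsa_amp * exp(rnorm(1, 0, config$base_sd$rsa_amp))
  lf0 <- b$lf_amp * exp(rnorm(1, 0, config$base_sd$lf_amp))
  rr0 <- min(0.95, max(0.08, rnorm(1, b$resp_rate, config$base_sd$resp_rate)))
  sp <- list()
  for (s in hyperbaric_stages()) {
    fac <- config$stage_factors[[s]]
    if (anomalous) fac <- 1 + config$anomaly_mult * (fac - 1)
    fac <- fac + rnorm(length(fac), 0, config$factor_jitter_sd)
    sp[[s]] <- list(mean_hr = min(180, max(30, hr0 * fac[["mean_hr"]])),
                    rsa_amp = max(0.002, rsa0 * fac[["rsa_amp"]]),
                    lf_amp = max(0.002, lf0 * fac[["lf_amp"]]),
                    resp_rate = min(1, max(0.07, rr0 * fac[["resp_rate"]])),
                    resp_rate_drift = b$resp_rate_drift,
                    noise_sd = b$noise_sd)
  }
  subject_profile(subject_id, sp, anomalous = anomalous)
}

#' Generate a synthetic hyperbaric cohort
#'
#' Draws subject profiles from the stage-effect template in
#' [cohort_config()] (anomalous subjects with opposed deviations), then
#' generates every subject-stage record with full ground truth.
#'
#' @param n_subjects number of subjects.
#' @param n_anomalous number of anomalous subjects (must be < `n_subjects`);
#'   they are assigned the highest subject ids.
#' @param config a [cohort_config()] list.
#' @param seed integer master seed.
#' @param level `"beats"` (fast, ground-truth beats + respiration) or
#'   `"ecg"` (full 3-lead ECG synthesis).
#' @return object of class `hrv_cohort`: list with `subjects` (each holding
#'   `profile` and per-stage `records`), `config`, `level`, `seed`.
#' @export
generate_cohort <- function(n_subjects = 28, n_anomalous = 6,
                            config = cohort_config(), seed = 1L,
                            level = c("beats", "ecg")) {
  level <- match.arg(level)
  if (n_anomalous >= n_subjects) stop("n_anomalous must be < n_subjects")
  set.seed(seed)
  anom <- rep(FALSE, n_subjects)
  if (n_anomalous > 0) anom[(n_subjects - n_anomalous + 1L):n_subjects] <- TRUE
  profile_seeds <- sample.int(2^30, n_subjects)
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    set.seed(profile_seeds[i])
    prof <- draw_profile(i, anom[i], config)
    records <- list()
    for (si in seq_along(hyperbaric_stages())) {
      s <- hyperbaric_stages()[si]
      records[[s]] <- generate_stage_record(
        prof, s, duration = config$stage_duration, fs = config$fs,
        seed = (profile_seeds[i] + 7919L * si) %% 2147483647L,
        level = level, hrv_noise = config$hrv_noise)
    }
    subjects[[i]] <- list(profile = prof, records = records)
  }
  structure(list(subjects = subjects, config = config, level = level,
                 seed = seed),
            class = "hrv_cohort")
}

#' @export
print.hrv_cohort <- function(x, ...) {
  n <- length(x$subjects)
  na <- sum(vapply(x$subjects, function(s) s$profile$anomalous, logical(1)))
  cat("Synthetic hyperbaric cohort:", n, "subjects (", na, "anomalous ),",
      length(hyperbaric_stages()), "stages of",
      x$config$stage_duration, "s, level =", x$level, "\n")
  invisible(x)
}

#' Anomalous-subject ids of a synthetic cohort
#' @param cohort an `hrv_cohort`.
#' @return integer vector of subject ids generated with an opposed response.
#' @export
anomalous_ids <- function(cohort) {
  which(vapply(cohort$subjects, function(s) s$profile$anomalous, logical(1)))
}
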