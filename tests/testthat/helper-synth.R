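# shared fixture builders (all synthetic, generated at test time)

make_profile <- function(mean_hr = 70, rsa_amp = 0.03, lf_amp = 0.03,
                         resp_rate = 0.3, drift = 0, noise_sd = 0,
                         anomalous = FALSE, id = 1L) {
  sp <- lapply(hyperbaric_stages(), function(s) {
    list(mean_hr = mean_hr, rsa_amp = rsa_amp, lf_amp = lf_amp,
         resp_rate = resp_rate, resp_rate_drift = drift, noise_sd = noise_sd)
  })
  names(sp) <- hyperbaric_stages()
  subject_profile(id, sp, anomalous = anomalous)
}

# ECG fixture with known beat times and respiratory modulation
make_ecg_fixture <- function(rate = 0.3, fs = 1000, duration = 120, seed = 7,
                             noise_sd = 0, mod_depth = 0.05, hrv_noise = 0,
                             mean_hr = 70, rsa_amp = 0.03, lf_amp = 0.03) {
  prof <- make_profile(mean_hr = mean_hr, rsa_amp = rsa_amp, lf_amp = lf_amp,
                       resp_rate = rate, noise_sd = noise_sd)
  bs <- generate_beat_series(prof, "1D", duration, seed = seed,
                             hrv_noise = hrv_noise)
  tt <- seq(0, duration, by = 1 / fs)
  resp <- sin(2 * pi * rate * tt)
  morph <- qrs_morphology(mod_depth = mod_depth, noise_sd = noise_sd)
  ecg <- generate_ecg(bs$beat_times, resp, morph = morph, fs = fs,
                      seed = seed + 1L, duration = duration)
  list(ecg = ecg, beat_times = bs$beat_times, resp = resp, rate = rate,
       fs = fs, m = bs$m, t4 = bs$t)
}

# feature table with one informative column and noise elsewhere, for
# classification tests (stages "5" vs "3A")
make_feature_table <- function(n_subjects = 16, d = 2, seed = 1,
                               informative = "f_r") {
  set.seed(seed)
  cols <- hrv_feature_names()
  rows <- list()
  for (s in seq_len(n_subjects)) {
    for (st in c("5", "3A")) {
      v <- stats::setNames(as.list(stats::rnorm(length(cols), 0, 1)), cols)
      v[[informative]] <- stats::rnorm(1, if (st == "5") d / 2 else -d / 2, 1)
      rows[[length(rows) + 1L]] <- cbind(data.frame(subject = s, stage = st),
                                         as.data.frame(v))
    }
  }
  do.call(rbind, rows)
}
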