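#' Per-stage HRV and respiratory parameters for one stage record
#'
#' Runs the full analysis chain for one subject-stage and returns the nine
#' parameters, computed over the stage's last four minutes: fused
#' respiratory rate, the four time-domain NN parameters, and the four OSP
#' frequency-domain parameters.
#'
#' For an ECG-level record the chain is: baseline removal, beat detection
#' on the second lead, ectopic correction, the nine EDR signals,
#' peaked-conditioned spectral fusion for the respiratory rate,
#' IPFM-inverse instantaneous heart rate, and OSP against the detection
#' lead's up-slope EDR signal. For a beat-level record the ground-truth
#' beats and respiration surrogate enter the same NN-correction, HRV,
#' fusion and OSP code directly.
#'
#' @param rec one stage record from [generate_stage_record()] (or a list
#'   with `ecg` and/or `truth` of the same shape).
#' @param window_len analysis window at the end of the stage (s).
#' @param detection_lead lead used for beat detection and as OSP
#'   respiration source.
#' @param max_delay OSP delay span in samples at 4 Hz.
#' @return one-row data.frame: `stage`, the columns of
#'   [hrv_feature_names()], `n_intervals`, `defined`.
#' @export
stage_features <- function(rec, window_len = 240, detection_lead = 2L,
                           max_delay = 40) {
  stage <- rec$stage
  if (!is.null(rec$ecg)) {
    record <- remove_baseline(rec$ecg)
    lead <- record$leads[, detection_lead]
    beats <- detect_beats(lead, record$fs)
    nn <- correct_ectopics(beats)
    edr <- edr_signals(record, beats)
    track <- track_resp_rate(edr)
    resp_t <- edr$t
    resp <- edr$x[, which(edr$lead == detection_lead & edr$kind == "Us")[1]]
    duration <- (nrow(record$leads) - 1L) / record$fs
  } else {
    nn <- correct_ectopics(rec$truth$beat_times)
    resp_t <- rec$truth$t4
    resp <- rec$truth$resp4
    track <- track_resp_rate(matrix(resp, ncol = 1L))
    duration <- max(resp_t)
  }
  t_start <- max(0, duration - window_len)
  tp <- time_params(nn, t_start = t_start, t_end = duration)
  hr <- instantaneous_hr(nn, t_out = resp_t)
  sh <- split_hrv(hr)
  win <- resp_t >= t_start & resp_t <= duration
  V <- build_resp_subspace(resp[win], max_delay = max_delay)
  fit <- osp_decompose(sh$hrv[win], V)
  fp <- component_powers(fit)
  f_r <- mean_resp_rate(track, t_start, duration)
  data.frame(stage = stage, f_r = f_r,
             nn_med = tp$nn_med, iqr_nn = tp$iqr_nn, rmssd = tp$rmssd,
             pnn50 = tp$pnn50,
             p_r = fp$p_r, p_perp = fp$p_perp,
             p_lf_perp = fp$p_lf_perp, p_hf_perp = fp$p_hf_perp,
             n_intervals = tp$n_intervals,
             defined = tp$defined && fp$defined)
}

#' Per-subject, per-stage parameter table for a cohort
#'
#' Applies [stage_features()] to every subject-stage record of a synthetic
#' cohort (or any list with the same shape).
#'
#' @param cohort an `hrv_cohort` from [generate_cohort()].
#' @param ... passed to [stage_features()].
#' @return data.frame with `subject`, `stage` and the parameter columns.
#' @export
cohort_features <- function(cohort, ...) {
  out <- list()
  for (sub in cohort$subjects) {
    for (rec in sub$records) {
      f <- stage_features(rec, ...)
      f$subject <- sub$profile$subject_id
      out[[length(out) + 1L]] <- f
    }
  }
  df <- do.call(rbind, out)
  df[, c("subject", setdiff(names(df), "subject"))]
}

#' Stage-relative feature ratios
#'
#' Converts a raw per-stage parameter table into the dimensionless
#' relative changes `R(Y_S) = (Y_S - Y_1D)/(Y_S + Y_1D)` against each
#' subject's baseline stage 1D, for the four non-baseline stages.
#'
#' @param features data.frame from [cohort_features()] (columns `subject`,
#'   `stage`, and the parameter columns of [hrv_feature_names()]).
#' @param reference reference stage label.
#' @return data.frame with `subject`, `stage` and the ratio columns, one
#'   row per subject and non-reference stage.
#' @export
feature_ratios <- function(features, reference = "1D") {
  cols <- hrv_feature_names()
  out <- list()
  for (s in unique(features$subject)) {
    base <- features[features$subject == s & features$stage == reference, ]
    if (nrow(base) != 1L) next
    for (st in setdiff(hyperbaric_stages(), reference)) {
      row <- features[features$subject == s & features$stage == st, ]
      if (nrow(row) != 1L) next
      r <- as.data.frame(lapply(cols, function(cc) {
        suppressWarnings(relative_change(row[[cc]], base[[cc]]))
      }))
      names(r) <- cols
      out[[length(out) + 1L]] <- cbind(data.frame(subject = s, stage = st), r)
    }
  }
  do.call(rbind, out)
}
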