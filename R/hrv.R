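#' Instantaneous heart rate from the IPFM inverse
#'
#' Under the integral pulse frequency modulation model the beat counter
#' crosses one integer per beat, so a smooth interpolant of beat index
#' against beat time has derivative equal to the instantaneous rate
#' `(1 + m(t)) * mean rate`. The rate is evaluated on a 4 Hz grid from the
#' derivative of a cubic spline through (beat time, beat index). Gaps
#' longer than `max_gap` seconds are bridged by the spline and flagged.
#'
#' @param beat_times corrected beat occurrence times (s), strictly
#'   increasing; either a numeric vector or an `nn_series` from
#'   [correct_ectopics()].
#' @param fs_out output sampling rate (Hz).
#' @param t_out optional output grid (s); defaults to the span of the beats
#'   at `fs_out`.
#' @param max_gap gap length (s) above which samples are flagged.
#' @return object of class `hr_signal`: list with `t`, `hr` (Hz),
#'   `flagged` (logical, samples inside long gaps).
#' @export
instantaneous_hr <- function(beat_times, fs_out = 4, t_out = NULL,
                             max_gap = 3) {
  if (inherits(beat_times, "nn_series")) beat_times <- beat_times$beat_times
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) < 4L) stop("need at least 4 beats")
  if (any(diff(beat_times) <= 0)) stop("beat_times must be strictly increasing")
  if (is.null(t_out)) {
    t_out <- seq(beat_times[1L], beat_times[length(beat_times)], by = 1 / fs_out)
  }
  sf <- stats::splinefun(beat_times, seq_along(beat_times) - 1L, method = "fmm")
  hr <- sf(t_out, deriv = 1L)
  hr <- pmax(hr, 0)
  gaps <- diff(beat_times)
  flagged <- rep(FALSE, length(t_out))
  for (g in which(gaps > max_gap)) {
    flagged <- flagged | (t_out > beat_times[g] & t_out < beat_times[g + 1L])
  }
  structure(list(t = t_out, hr = hr, flagged = flagged, fs = fs_out),
            class = "hr_signal")
}

#' @export
print.hr_signal <- function(x, ...) {
  cat(sprintf("Instantaneous HR: %.0f s at %g Hz, mean %.1f bpm\n",
              max(x$t) - min(x$t), x$fs, 60 * mean(x$hr)))
  invisible(x)
}

#' Split heart rate into mean rate and variability
#'
#' The mean heart rate is the zero-phase low-pass (0.03 Hz) component of
#' the instantaneous rate; the HRV signal is the exact remainder
#' `HRV = HR - mHR`, so the two always add back to HR. With
#' `normalized = TRUE` the modulating-signal estimate `(HR - mHR) / mHR`
#' is returned instead of the difference.
#'
#' @param hr an `hr_signal` from [instantaneous_hr()].
#' @param cutoff mean-rate cut-off (Hz).
#' @param normalized return the mean-rate-compensated modulation estimate.
#' @return list with `t`, `mhr`, `hrv` (all on the input grid).
#' @export
split_hrv <- function(hr, cutoff = 0.03, normalized = FALSE) {
  stopifnot(inherits(hr, "hr_signal"))
  if (max(hr$t) - min(hr$t) < 2 / cutoff) {
    stop("record shorter than twice the mean-rate filter memory")
  }
  mhr <- lowpass_trend(hr$hr, hr$fs, cutoff)
  hrv <- hr$hr - mhr
  if (normalized) hrv <- hrv / mhr
  list(t = hr$t, mhr = mhr, hrv = hrv)
}

#' Time-domain HRV parameters of a stage window
#'
#' Computes, over the NN intervals whose end times fall inside the window:
#' the median NN interval, its interquartile range, the root mean square of
#' successive differences, and the percentage of successive-difference
#' pairs exceeding 50 ms. The percentage uses the interval count as
#' denominator by default (`pnn50_denom = "intervals"`); the conventional
#' difference-count denominator is available with `pnn50_denom = "diffs"`.
#'
#' @param nn an `nn_series` from [correct_ectopics()], or a numeric vector
#'   of NN intervals in seconds (then `t_start`/`t_end` are ignored).
#' @param t_start,t_end stage window in seconds.
#' @param min_intervals minimum interval count below which the result is
#'   flagged undefined.
#' @param pnn50_denom denominator convention for pNN50.
#' @return data.frame with `nn_med` (s), `iqr_nn` (s), `rmssd` (s),
#'   `pnn50` (%), `n_intervals`, `defined`.
#' @export
time_params <- function(nn, t_start = -Inf, t_end = Inf, min_intervals = 30,
                        pnn50_denom = c("intervals", "diffs")) {
  pnn50_denom <- match.arg(pnn50_denom)
  if (inherits(nn, "nn_series")) {
    sel <- nn$t >= t_start & nn$t <= t_end
    x <- nn$nn[sel]
  } else {
    x <- as.numeric(nn)
  }
  n <- length(x)
  if (n < min_intervals) {
    return(data.frame(nn_med = NA_real_, iqr_nn = NA_real_, rmssd = NA_real_,
                      pnn50 = NA_real_, n_intervals = n, defined = FALSE))
  }
  d <- diff(x)
  denom <- if (pnn50_denom == "intervals") n else length(d)
  data.frame(
    nn_med = stats::median(x),
    iqr_nn = unname(stats::quantile(x, 0.75) - stats::quantile(x, 0.25)),
    rmssd = sqrt(mean(d^2)),
    pnn50 = 100 * sum(abs(d) > 0.050) / denom,
    n_intervals = n,
    defined = TRUE
  )
}
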