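#' Locate the maximum-variation points of the QRS flanks
#'
#' For each beat, finds the sample of steepest upward slope between the Q
#' and R fiducials (maximum of the lead's first derivative) and the sample
#' of steepest downward slope between R and S (maximum of the derivative's
#' magnitude, i.e. the most negative derivative for an upright QRS). Ties
#' take the earliest sample. Beats with a degenerate window (Q = R or
#' R = S) are dropped and flagged.
#'
#' @param lead baseline-removed ECG lead (mV).
#' @param fs sampling frequency (Hz).
#' @param beats a `beat_annotations` object with per-beat Q, R, S times.
#' @return list with `n_u`, `n_d` (times in s), `beat` (index into the
#'   input beats), `dropped` (indices of skipped beats).
#' @export
locate_slope_points <- function(lead, fs, beats) {
  d <- c(0, diff(lead)) * fs / 1000  # mV/ms
  to_idx <- function(t) round(t * fs) + 1L
  nb <- length(beats$r_times)
  n_u <- n_d <- numeric(nb)
  ok <- logical(nb)
  for (i in seq_len(nb)) {
    qi <- to_idx(beats$q_times[i]); ri <- to_idx(beats$r_times[i]); si <- to_idx(beats$s_times[i])
    if (qi >= ri || ri >= si) next
    up <- qi:ri
    iu <- up[which.max(d[up])]           # earliest on ties (which.max)
    dn <- ri:si
    id <- dn[which.max(abs(d[dn]))]
    n_u[i] <- (iu - 1L) / fs
    n_d[i] <- (id - 1L) / fs
    ok[i] <- TRUE
  }
  list(n_u = n_u[ok], n_d = n_d[ok], beat = which(ok), dropped = which(!ok))
}

#' Least-squares R-wave slopes
#'
#' Fits an ordinary least-squares straight line to the lead inside an 8 ms
#' window centred on each maximum-variation point and reports its slope in
#' mV/ms. The window uses the nearest odd number of samples at the given
#' sampling rate; beats whose window is truncated by the record edge are
#' skipped.
#'
#' @inheritParams locate_slope_points
#' @param n_u,n_d times (s) from [locate_slope_points()].
#' @param window_ms full fit-window length in milliseconds.
#' @return list with `i_us`, `i_ds` (mV/ms) and `keep` (logical, beats with
#'   both windows inside the record).
#' @export
fit_slopes <- function(lead, fs, n_u, n_d, window_ms = 8) {
  half <- max(1L, round(window_ms / 2 * fs / 1000))
  n <- length(lead)
  x_ms <- (seq(-half, half)) / fs * 1000
  sxx <- sum((x_ms - mean(x_ms))^2)
  slope_at <- function(t) {
    c0 <- round(t * fs) + 1L
    if (c0 - half < 1L || c0 + half > n) return(NA_real_)
    y <- lead[(c0 - half):(c0 + half)]
    sum((x_ms - mean(x_ms)) * (y - mean(y))) / sxx
  }
  i_us <- vapply(n_u, slope_at, numeric(1))
  i_ds <- vapply(n_d, slope_at, numeric(1))
  keep <- !is.na(i_us) & !is.na(i_ds)
  list(i_us = i_us, i_ds = i_ds, keep = keep)
}

#' R-wave angle
#'
#' Angle between the fitted up-slope and down-slope lines after the fixed
#' axis scaling used with slopes expressed in mV/ms:
#' `phi = arctan((i_us - i_ds) / (0.4 * (6.25 + i_us * i_ds)))`.
#' A vanishing denominator (i_us * i_ds = -6.25) gives the right-angle
#' limit `pi/2` (signed by the numerator).
#'
#' @param i_us,i_ds up- and down-slopes in mV/ms.
#' @return angle in radians.
#' @export
rwave_angle <- function(i_us, i_ds) {
  num <- i_us - i_ds
  den <- 0.4 * (6.25 + i_us * i_ds)
  phi <- atan2(num, den)
  # atan2 maps den < 0 into the second quadrant; fold back to the smallest
  # angle between the two lines as atan would, keeping the den = 0 limit
  phi <- ifelse(phi > pi / 2, phi - pi, ifelse(phi < -pi / 2, phi + pi, phi))
  ifelse(den == 0 & num == 0, pi / 2, phi)
}

#' Condition a beat-indexed series into an evenly sampled EDR signal
#'
#' Places per-beat values at their beat occurrence times, rejects outliers
#' deviating from the median by more than `mad_c` times the median absolute
#' deviation, resamples to 4 Hz with a cubic spline and applies a
#' zero-phase 0.07-1 Hz band-pass so only respiratory-band content remains.
#'
#' @param values per-beat values (slope or angle series).
#' @param beat_times matching beat occurrence times (s).
#' @param t_out output time grid (s, 4 Hz spacing); defaults to the record
#'   span.
#' @param mad_c outlier rejection constant.
#' @param band pass-band edges in Hz.
#' @return list with `t`, `x` (the filtered EDR signal) and `rejected`
#'   (count of outliers removed).
#' @export
build_edr_signal <- function(values, beat_times, t_out = NULL, mad_c = 5,
                             band = c(0.07, 1)) {
  stopifnot(length(values) == length(beat_times))
  if (length(values) < 10L) stop("need at least 10 valid beats")
  med <- stats::median(values)
  madv <- stats::mad(values)
  keep <- if (madv > 0) abs(values - med) <= mad_c * madv else rep(TRUE, length(values))
  if (!any(keep)) stop("all beat values rejected as outliers")
  if (sum(keep) < 4L) stop("too few beat values after outlier rejection")
  if (is.null(t_out)) t_out <- seq(0, max(beat_times), by = 0.25)
  xs <- stats::spline(beat_times[keep], values[keep], xout = t_out, method = "natural")$y
  xf <- fft_filter(xs, fs = 1 / (t_out[2] - t_out[1]), low = band[1], high = band[2],
                   trans = 0.06)
  list(t = t_out, x = xf, rejected = sum(!keep))
}

#' The nine ECG-derived respiration signals of a 3-lead record
#'
#' For every lead: refines the R fiducial locally, locates Q and S, finds
#' the maximum-variation points, fits the 8 ms least-squares slopes and the
#' R-wave angle, and conditions the three beat-indexed series (up-slope Us,
#' down-slope Ds, angle Ra) into 4 Hz band-limited respiration surrogates.
#'
#' @param record a baseline-removed [ecg_record()].
#' @param beats `beat_annotations` from the detection lead.
#' @param t_out optional common 4 Hz output grid.
#' @param mad_c outlier-rejection constant, see [build_edr_signal()].
#' @return object of class `edr_set`: list with `t` (4 Hz grid), `x`
#'   (matrix, one column per EDR signal), `kind`, `lead` (per column), and
#'   `slope_series` (per-lead data.frames with the raw beat-indexed values).
#' @export
edr_signals <- function(record, beats, t_out = NULL, mad_c = 5) {
  stopifnot(inherits(record, "ecg_record"))
  fs <- record$fs
  if (is.null(t_out)) {
    t_out <- seq(0, (nrow(record$leads) - 1L) / fs, by = 0.25)
  }
  n_leads <- ncol(record$leads)
  cols <- list(); kind <- character(0); lead_of <- integer(0)
  slope_series <- list()
  for (l in seq_len(n_leads)) {
    lead <- record$leads[, l]
    # per-lead fiducials: refine R near the detection-lead R, then Q/S
    b <- refine_fiducials(lead, fs, beats)
    sp <- locate_slope_points(lead, fs, b)
    sl <- fit_slopes(lead, fs, sp$n_u, sp$n_d)
    ok <- sl$keep
    bt <- b$r_times[sp$beat][ok]
    i_us <- sl$i_us[ok]; i_ds <- sl$i_ds[ok]
    phi <- rwave_angle(i_us, i_ds)
    slope_series[[l]] <- data.frame(beat_time = bt, n_u = sp$n_u[ok],
                                    n_d = sp$n_d[ok], i_us = i_us,
                                    i_ds = i_ds, phi = phi)
    for (kd in c("Us", "Ds", "Ra")) {
      v <- switch(kd, Us = i_us, Ds = i_ds, Ra = phi)
      e <- build_edr_signal(v, bt, t_out = t_out, mad_c = mad_c)
      cols[[length(cols) + 1L]] <- e$x
      kind <- c(kind, kd); lead_of <- c(lead_of, l)
    }
  }
  structure(list(t = t_out, x = do.call(cbind, cols), kind = kind,
                 lead = lead_of, slope_series = slope_series, fs = 4),
            class = "edr_set")
}

#' @export
print.edr_set <- function(x, ...) {
  cat(sprintf("EDR set: %d signals (%d leads x %s) at 4 Hz, %.0f s\n",
              ncol(x$x), length(unique(x$lead)),
              paste(unique(x$kind), collapse = "/"),
              max(x$t)))
  invisible(x)
}

# refine detection-lead fiducials on another lead: R = local max within
# +/-50 ms of the detected R, then Q/S windows as in detect_beats
refine_fiducials <- function(lead, fs, beats) {
  n <- length(lead)
  half <- as.integer(round(0.05 * fs))
  q_lo <- as.integer(round(0.060 * fs)); q_hi <- as.integer(max(1, round(0.004 * fs)))
  s_lo <- as.integer(max(1, round(0.004 * fs))); s_hi <- as.integer(round(0.100 * fs))
  r_idx <- vapply(as.integer(round(beats$r_times * fs)) + 1L, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    lo + which.max(lead[lo:hi]) - 1L
  }, integer(1))
  keep <- r_idx - q_lo >= 1L & r_idx + s_hi <= n
  r_idx <- r_idx[keep]
  q_idx <- vapply(r_idx, function(i) {
    w <- (i - q_lo):(i - q_hi); w[which.min(lead[w])]
  }, integer(1))
  s_idx <- vapply(r_idx, function(i) {
    w <- (i + s_lo):(i + s_hi); w[which.min(lead[w])]
  }, integer(1))
  new_beat_annotations((r_idx - 1L) / fs, (q_idx - 1L) / fs, (s_idx - 1L) / fs)
}
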