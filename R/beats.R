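#' Beat annotations
#'
#' R, Q and S fiducial times per detected beat. Q and S are located as the
#' minima of the (baseline-removed) lead in search windows before and after
#' each R peak; beats whose search window is truncated by the record edge
#' are dropped.
#'
#' @name beat_annotations
NULL

new_beat_annotations <- function(r_times, q_times, s_times, validity = NULL) {
  if (is.null(validity)) validity <- rep("normal", length(r_times))
  structure(list(r_times = r_times, q_times = q_times, s_times = s_times,
                 validity = validity),
            class = "beat_annotations")
}

#' @export
print.beat_annotations <- function(x, ...) {
  cat("Beat annotations:", length(x$r_times), "beats")
  if (length(x$r_times) > 1L) {
    cat(sprintf(", mean HR %.1f bpm", 60 / mean(diff(x$r_times))))
  }
  cat("\n")
  invisible(x)
}

# keep local maxima at least min_dist samples apart, preferring the higher
peaks_min_distance <- function(y, idx, min_dist) {
  if (length(idx) == 0L) return(idx)
  ord <- idx[order(y[idx], decreasing = TRUE)]
  keep <- logical(0)
  taken <- integer(0)
  for (i in ord) {
    if (length(taken) == 0L || min(abs(taken - i)) >= min_dist) {
      taken <- c(taken, i)
    }
  }
  sort(taken)
}

#' Detect heartbeats in one ECG lead
#'
#' Energy/adaptive-threshold QRS detector: the lead is band-pass filtered
#' to the QRS energy band (10-45 Hz), squared and smoothed by an 80 ms
#' moving-window integrator; the peak-height population of the integrated
#' signal is split into noise and QRS clusters by a deterministic
#' two-means pass, peaks above the mid-gap threshold and outside a 250 ms
#' refractory period mark beats, and long gaps (over 1.66 times the
#' running median RR) are revisited at half threshold until no gap
#' remains. Each R peak is then refined to the maximum
#' of the raw lead within +/-60 ms, and Q and S are taken as the minima in
#' \[R-60, R-4\] ms and \[R+4, R+100\] ms.
#'
#' @param lead numeric vector, baseline-removed ECG lead in mV.
#' @param fs sampling frequency in Hz.
#' @param refractory minimum beat separation in seconds.
#' @return a `beat_annotations` object (empty, with a warning, if no beats
#'   are found).
#' @export
detect_beats <- function(lead, fs, refractory = 0.25) {
  n <- length(lead)
  empty <- new_beat_annotations(numeric(0), numeric(0), numeric(0))
  if (n < fs) {
    warning("record too short for beat detection")
    return(empty)
  }
  bp <- fft_filter(lead, fs, low = 10, high = 45)
  sq <- bp^2
  wlen <- max(3L, as.integer(round(0.08 * fs)))
  mwi <- stats::filter(sq, rep(1 / wlen, wlen), sides = 2)
  mwi[is.na(mwi)] <- 0
  mwi <- as.numeric(mwi)
  if (stats::quantile(mwi, 0.99) <= 1e-12) {
    warning("no beats found")
    return(empty)
  }
  # split the peak-height population into noise and QRS clusters with a
  # deterministic two-means pass, then threshold mid-gap
  pk_all <- peaks_min_distance(mwi, local_maxima(mwi), round(0.12 * fs))
  h <- mwi[pk_all]
  c_lo <- unname(stats::quantile(h, 0.05))
  c_hi <- unname(stats::quantile(h, 0.98))
  for (it in 1:25) {
    mid <- (c_lo + c_hi) / 2
    c_lo_new <- mean(h[h <= mid])
    c_hi_new <- mean(h[h > mid])
    if (is.nan(c_lo_new) || is.nan(c_hi_new)) break
    if (abs(c_lo_new - c_lo) + abs(c_hi_new - c_hi) < 1e-12 * c_hi) break
    c_lo <- c_lo_new; c_hi <- c_hi_new
  }
  thr <- c_lo + 0.5 * (c_hi - c_lo)
  refr_n <- round(refractory * fs)
  cand <- peaks_min_distance(mwi, pk_all[h > thr], refr_n)
  # search-back: revisit long gaps with half the threshold, repeatedly,
  # taking the strongest qualifying peak per gap
  if (length(cand) >= 3L) {
    for (pass in 1:5) {
      rr_med <- stats::median(diff(cand))
      gaps <- which(diff(cand) > 1.66 * rr_med)
      if (length(gaps) == 0L) break
      extra <- integer(0)
      for (g in gaps) {
        lo <- cand[g] + refr_n
        hi <- cand[g + 1L] - refr_n
        if (hi <= lo) next
        seg <- pk_all[pk_all >= lo & pk_all <= hi]
        seg <- seg[mwi[seg] > thr / 2]
        if (length(seg)) extra <- c(extra, seg[which.max(mwi[seg])])
      }
      if (length(extra) == 0L) break
      cand <- sort(unique(as.integer(c(cand, extra))))
    }
  }
  if (length(cand) == 0L) {
    warning("no beats found")
    return(empty)
  }
  # refine R on the raw lead; MWI peaks lag the R wave by roughly half the
  # integration window
  half <- as.integer(round(0.06 * fs))
  r_idx <- vapply(cand, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    lo + which.max(lead[lo:hi]) - 1L
  }, integer(1))
  r_idx <- sort(unique(r_idx))
  q_lo <- as.integer(round(0.060 * fs)); q_hi <- as.integer(max(1, round(0.004 * fs)))
  s_lo <- as.integer(max(1, round(0.004 * fs))); s_hi <- as.integer(round(0.100 * fs))
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

#' Correct ectopic, missed and false beats
#'
#' Flags RR intervals deviating from a 5-point running median by more than
#' `factor` times that median, then rectifies them: two adjacent short
#' flagged intervals whose sum matches the local median are merged (false
#' detection), a flagged interval near a multiple of the median is split
#' evenly (missed beats), and any remaining flagged interval is replaced by
#' spline interpolation across its neighbours (ectopic timing). The result
#' is the normal-to-normal (NN) interval series.
#'
#' @param beats a `beat_annotations` object or a numeric vector of beat
#'   times in seconds (>= 3 beats).
#' @param factor flagging threshold as a fraction of the running median.
#' @return object of class `nn_series`: list with `nn` (intervals, s),
#'   `t` (time at the end of each interval, s), `beat_times` (corrected),
#'   `flagged_frac` (fraction of original intervals flagged).
#' @export
correct_ectopics <- function(beats, factor = 0.3) {
  r_times <- if (inherits(beats, "beat_annotations")) beats$r_times else as.numeric(beats)
  if (length(r_times) < 3L) stop("need at least 3 beats")
  rr <- diff(r_times)
  nrr <- length(rr)
  k <- min(5L, if (nrr %% 2L == 1L) nrr else nrr - 1L)
  med <- if (k >= 3L) stats::runmed(rr, k, endrule = "median") else rep(stats::median(rr), nrr)
  flag <- abs(rr - med) > factor * med
  if (mean(flag) > 0.2) {
    warning(sprintf("%.0f%% of intervals flagged: poor record quality", 100 * mean(flag)))
  }
  out <- numeric(0)
  out_flag <- logical(0)
  i <- 1L
  while (i <= nrr) {
    if (!flag[i]) {
      out <- c(out, rr[i]); out_flag <- c(out_flag, FALSE); i <- i + 1L
    } else if (i < nrr && flag[i + 1L] &&
               abs(rr[i] + rr[i + 1L] - med[i]) <= factor * med[i]) {
      # false detection: merge the split interval
      out <- c(out, rr[i] + rr[i + 1L]); out_flag <- c(out_flag, TRUE); i <- i + 2L
    } else if (rr[i] > (2 - factor) * med[i]) {
      # missed beat(s): split evenly
      ks <- max(2L, round(rr[i] / med[i]))
      out <- c(out, rep(rr[i] / ks, ks)); out_flag <- c(out_flag, rep(TRUE, ks)); i <- i + 1L
    } else {
      out <- c(out, NA_real_); out_flag <- c(out_flag, TRUE); i <- i + 1L
    }
  }
  if (anyNA(out)) {
    ok <- which(!is.na(out))
    if (length(ok) >= 2L) {
      out[-ok] <- stats::spline(ok, out[ok], xout = which(is.na(out)))$y
    } else {
      out[is.na(out)] <- stats::median(rr)
    }
  }
  beat_times <- r_times[1L] + cumsum(c(0, out))
  structure(list(nn = out, t = beat_times[-1L], beat_times = beat_times,
                 flagged = out_flag, flagged_frac = mean(flag)),
            class = "nn_series")
}

#' @export
print.nn_series <- function(x, ...) {
  cat(sprintf("NN series: %d intervals, median %.3f s, %.1f%% corrected\n",
              length(x$nn), stats::median(x$nn), 100 * mean(x$flagged)))
  invisible(x)
}
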