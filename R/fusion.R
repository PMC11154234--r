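#' Welch spectrum of one EDR analysis window
#'
#' PSD of a 40 s EDR window at 4 Hz using 12 s Hamming sub-windows with 50%
#' overlap, zero-padded to a grid finer than 0.005 Hz. A window with more
#' than 25% missing samples is flagged unusable.
#'
#' @param x numeric vector (one EDR analysis window at `fs`).
#' @param fs sampling frequency (Hz).
#' @param seg_len Welch sub-window length (s).
#' @param nfft zero-padded transform length.
#' @return list `f`, `psd`, `usable`.
#' @export
welch_spectrum <- function(x, fs = 4, seg_len = 12, nfft = 1024) {
  usable <- mean(is.na(x)) <= 0.25
  if (anyNA(x)) x[is.na(x)] <- stats::median(x, na.rm = TRUE)
  s <- welch_psd(x, fs, seg_len = seg_len, nfft = nfft)
  c(s, list(usable = usable))
}

spec_power <- function(spec, lo, hi) {
  df <- spec$f[2] - spec$f[1]
  sum(spec$psd[spec$f >= lo & spec$f <= hi]) * df
}

#' Select the respiratory peak of one spectrum
#'
#' Finds the global spectral maximum `f_i`, then all local maxima inside
#' the reference interval `[prev - delta, prev + 2 delta]` whose height is
#' at least `height_frac` of the global peak, and selects `f_ii` as the
#' candidate nearest to the previous estimate. Peakness is the percentage
#' of the reference-interval power concentrated within
#' `+/- pk_halfwidth` of `f_ii`.
#'
#' @param spec list with `f`, `psd` (from [welch_spectrum()]).
#' @param prev previous respiratory-rate estimate (Hz).
#' @param delta reference-interval parameter (Hz).
#' @param height_frac candidate height threshold relative to the global peak.
#' @param pk_halfwidth peakness window half-width (Hz). The default
#'   (0.1 Hz) spans the mainlobe of the 12 s Hamming sub-windows, so a
#'   clean respiratory line scores near 100% while diffuse spectra fail
#'   the 85% gate.
#' @param band admissible respiratory band (Hz).
#' @return list `f_i`, `f_ii` (NA if no candidate), `peakness` (%, 0 if no
#'   candidate).
#' @export
select_peak <- function(spec, prev, delta = 0.1, height_frac = 0.85,
                        pk_halfwidth = 0.1, band = c(0.07, 1)) {
  inb <- spec$f >= band[1] & spec$f <= band[2]
  f <- spec$f[inb]; p <- spec$psd[inb]
  f_i <- f[which.max(p)]
  h_i <- max(p)
  lo <- max(band[1], prev - delta); hi <- min(band[2], prev + 2 * delta)
  lm <- local_maxima(p)
  cand <- lm[f[lm] >= lo & f[lm] <= hi & p[lm] >= height_frac * h_i]
  # the global maximum itself counts as a candidate when inside the interval
  gi <- which.max(p)
  if (f_i >= lo && f_i <= hi) cand <- sort(unique(c(cand, gi)))
  if (length(cand) == 0L) {
    return(list(f_i = f_i, f_ii = NA_real_, peakness = 0))
  }
  f_ii <- f[cand[which.min(abs(f[cand] - prev))]]
  p_ref <- spec_power(spec, lo, hi)
  p_pk <- spec_power(spec, f_ii - pk_halfwidth, f_ii + pk_halfwidth)
  pk <- if (p_ref > 0) 100 * min(1, p_pk / p_ref) else 0
  list(f_i = f_i, f_ii = f_ii, peakness = pk)
}

#' Sum spectra passing the peakness criteria
#'
#' @param psd_mat matrix of spectra (one column each) on a common grid.
#' @param chi logical/0-1 vector, one per column.
#' @return fused spectrum vector (zero vector if nothing selected).
#' @export
fuse_spectra <- function(psd_mat, chi) {
  stopifnot(ncol(psd_mat) == length(chi))
  as.numeric(psd_mat %*% as.numeric(chi))
}

#' Respiratory-rate peak of a fused spectrum
#'
#' @param psd fused spectrum vector.
#' @param f matching frequency grid (Hz).
#' @param omega restriction interval `c(lo, hi)` in Hz.
#' @return frequency of the maximum within `omega`.
#' @export
estimate_fr <- function(psd, f, omega = range(f)) {
  sel <- which(f >= omega[1] & f <= omega[2])
  f[sel[which.max(psd[sel])]]
}

#' Respiratory-rate track by peaked-conditioned spectral fusion
#'
#' Estimates the respiratory rate every 5 s from the nine EDR signals.
#' For each 40 s running window a Welch spectrum is computed per signal;
#' spectra are admitted to the fused average only if their peakness is at
#' least 85% (criterion A) and their power inside the current reference
#' interval is within `lambda` (relative) of the strongest signal of the
#' same window (criterion B; `criterion_b = "peakness"` instead compares
#' peakness normalised to \[0, 1\] within `lambda` of the best signal).
#' Admitted spectra
#' from the `2 Ls + 1` windows around k (symmetric mode; the past `2 Ls + 1`
#' windows in causal mode) are summed and the rate is the peak of the fused
#' spectrum inside the reference interval
#' `[F_R(k-1) - delta, F_R(k-1) + 2 delta]`, which bounds the step between
#' consecutive estimates by construction. If no spectrum qualifies the
#' previous rate and fused spectrum are held. The track is initialised from
#' the first window by a majority vote over the nine largest-peak
#' locations. Symmetric mode runs a causal first pass to fix the admission
#' flags, then re-fuses with the symmetric pooling.
#'
#' @param edr an `edr_set` from [edr_signals()], or a numeric matrix of
#'   band-limited respiration surrogates (one column per signal) at `fs`.
#' @param fs sampling rate of the EDR signals (Hz).
#' @param win,step analysis window length and hop (s).
#' @param Ls pooling half-width in windows (each signal contributes at most
#'   `2 Ls + 1` spectra per fused window).
#' @param delta reference-interval parameter (Hz).
#' @param lambda criterion-B tolerance.
#' @param peak_thresh criterion-A peakness threshold (%).
#' @param pk_halfwidth peakness window half-width (Hz), see [select_peak()].
#' @param criterion_b `"peakness"` or `"power"`, see Details.
#' @param mode `"symmetric"` (10 s output latency) or `"causal"`.
#' @param band admissible respiratory band (Hz).
#' @param nfft zero-padded transform length (grid spacing `fs / nfft`).
#' @param normalize scale each admitted spectrum to unit total power
#'   before summing, so the surrogates (slopes in mV/ms, angles in rad)
#'   vote on a common scale; the admission criteria always see the raw
#'   spectra.
#' @return object of class `resp_track`: data.frame with `k`, `t` (window
#'   centre, s), `f_r` (Hz), `n_averaged`.
#' @export
track_resp_rate <- function(edr, fs = 4, win = 40, step = 5, Ls = 2,
                            delta = 0.1, lambda = 0.05, peak_thresh = 85,
                            pk_halfwidth = 0.1,
                            criterion_b = c("power", "peakness"),
                            mode = c("symmetric", "causal"),
                            band = c(0.07, 1), nfft = 1024,
                            normalize = TRUE) {
  criterion_b <- match.arg(criterion_b)
  mode <- match.arg(mode)
  x <- if (inherits(edr, "edr_set")) edr$x else as.matrix(edr)
  ns <- ncol(x)
  n <- nrow(x)
  wlen <- round(win * fs)
  hop <- round(step * fs)
  if (n < wlen) stop("record shorter than one analysis window")
  starts <- seq(1L, n - wlen + 1L, by = hop)
  K <- length(starts)
  fgrid <- seq(0, fs / 2, length.out = nfft %/% 2L + 1L)
  # spectra for all windows x signals
  S <- array(NA_real_, dim = c(length(fgrid), K, ns))
  usable <- matrix(TRUE, K, ns)
  for (k in seq_len(K)) {
    for (j in seq_len(ns)) {
      sp <- welch_spectrum(x[starts[k]:(starts[k] + wlen - 1L), j], fs = fs,
                           nfft = nfft)
      S[, k, j] <- sp$psd
      usable[k, j] <- sp$usable
    }
  }
  power_tot <- apply(S, c(2, 3), function(p) sum(p) * (fgrid[2] - fgrid[1]))
  # spectra to be summed: slopes (mV/ms) and angles (rad) carry
  # incommensurate units, so each admitted spectrum is normalised to unit
  # power and the fused spectrum becomes an ensemble vote; the admission
  # criteria keep operating on the raw spectra
  Sf <- S
  if (normalize) {
    for (k in seq_len(K)) for (j in seq_len(ns)) {
      if (power_tot[k, j] > 0) Sf[, k, j] <- S[, k, j] / power_tot[k, j]
    }
  }

  # initial estimate: majority vote over the largest-peak locations of the
  # first window's spectra, binned at 0.02 Hz
  inb <- fgrid >= band[1] & fgrid <= band[2]
  f_i0 <- vapply(seq_len(ns), function(j) {
    fgrid[inb][which.max(S[inb, 1, j])]
  }, numeric(1))
  # spectra with no in-band power cannot vote
  has_power <- vapply(seq_len(ns), function(j) max(S[inb, 1, j]) > 0, logical(1))
  if (any(has_power)) f_i0 <- f_i0[has_power]
  bins <- round(f_i0 / 0.02)
  modal <- as.integer(names(sort(table(bins), decreasing = TRUE))[1])
  f0 <- stats::median(f_i0[bins == modal])

  causal_pass <- function() {
    fr <- numeric(K)
    chi <- matrix(FALSE, K, ns)
    pk <- matrix(0, K, ns)
    sbar_prev <- NULL
    prev <- f0
    for (k in seq_len(K)) {
      sel <- vapply(seq_len(ns), function(j) {
        sp <- list(f = fgrid, psd = S[, k, j])
        out <- select_peak(sp, prev, delta = delta,
                           pk_halfwidth = pk_halfwidth, band = band)
        out$peakness
      }, numeric(1))
      pk[k, ] <- ifelse(usable[k, ], sel, 0)
      chi_a <- pk[k, ] >= peak_thresh
      chi_b <- if (criterion_b == "peakness") {
        pk[k, ] / 100 >= max(pk[k, ]) / 100 - lambda
      } else {
        # power inside the current reference interval: rewards the
        # strength of the respiratory line, not broadband noise
        o_lo <- max(band[1], prev - delta); o_hi <- min(band[2], prev + 2 * delta)
        osel <- fgrid >= o_lo & fgrid <= o_hi
        p_ref <- colSums(matrix(S[osel, k, ], ncol = ns)) * (fgrid[2] - fgrid[1])
        p_ref >= (1 - lambda) * max(p_ref)
      }
      chi[k, ] <- chi_a & chi_b
      # causal pooling over the last 2Ls+1 windows
      lwin <- max(1L, k - 2L * Ls):k
      flags <- as.vector(chi[lwin, , drop = FALSE])
      sbar <- fuse_spectra(matrix(Sf[, lwin, , drop = FALSE],
                                  nrow = length(fgrid)), flags)
      if (sum(flags) == 0L) {
        fr[k] <- prev
        if (!is.null(sbar_prev)) sbar <- sbar_prev
      } else {
        omega <- c(max(band[1], prev - delta), min(band[2], prev + 2 * delta))
        fr[k] <- estimate_fr(sbar, fgrid, omega)
        sbar_prev <- sbar
      }
      prev <- fr[k]
    }
    list(fr = fr, chi = chi)
  }

  cp <- causal_pass()
  fr <- cp$fr
  n_avg <- integer(K)
  if (mode == "symmetric") {
    chi <- cp$chi
    prev <- f0
    sbar_prev <- NULL
    for (k in seq_len(K)) {
      lwin <- max(1L, k - Ls):min(K, k + Ls)
      flags <- as.vector(chi[lwin, , drop = FALSE])
      sbar <- fuse_spectra(matrix(Sf[, lwin, , drop = FALSE],
                                  nrow = length(fgrid)), flags)
      n_avg[k] <- sum(flags)
      if (n_avg[k] == 0L) {
        fr[k] <- prev
        if (!is.null(sbar_prev)) sbar <- sbar_prev
      } else {
        omega <- c(max(band[1], prev - delta), min(band[2], prev + 2 * delta))
        fr[k] <- estimate_fr(sbar, fgrid, omega)
        sbar_prev <- sbar
      }
      prev <- fr[k]
    }
  } else {
    chi <- cp$chi
    for (k in seq_len(K)) {
      lwin <- max(1L, k - 2L * Ls):k
      n_avg[k] <- sum(chi[lwin, ])
    }
  }
  structure(data.frame(k = seq_len(K),
                       t = (starts - 1L) / fs + win / 2,
                       f_r = fr, n_averaged = n_avg),
            class = c("resp_track", "data.frame"))
}

#' @export
print.resp_track <- function(x, ...) {
  cat(sprintf("Respiratory-rate track: %d estimates every %.0f s, median %.3f Hz\n",
              nrow(x), stats::median(diff(x$t)), stats::median(x$f_r)))
  invisible(x)
}

#' Mean respiratory rate over a time window
#'
#' @param track a `resp_track`.
#' @param t_start,t_end window in seconds (window centres within the range
#'   are averaged).
#' @return mean rate in Hz.
#' @export
mean_resp_rate <- function(track, t_start = -Inf, t_end = Inf) {
  sel <- track$t >= t_start & track$t <= t_end
  mean(track$f_r[sel])
}
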