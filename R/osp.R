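#' Respiratory subspace of delayed respiration signals
#'
#' Builds the design matrix whose columns are the mean-centred respiration
#' signal delayed by 0 ... `max_delay` samples (one-sided by default; set
#' `two_sided = TRUE` for delays -max_delay ... +max_delay). The first
#' `max_delay` rows, where delayed copies would run off the window, are
#' trimmed; use `attr(V, "rows")` to align other signals to the same rows.
#'
#' @param resp respiration signal over the stage window (numeric vector at
#'   4 Hz).
#' @param max_delay maximum delay in samples (default 40 = 10 s at 4 Hz).
#' @param two_sided include negative delays.
#' @return matrix `V` with attribute `rows` (indices of the retained rows
#'   in the input window).
#' @export
build_resp_subspace <- function(resp, max_delay = 40, two_sided = FALSE) {
  n <- length(resp)
  if (n <= 3 * max_delay) stop("window too short for the requested delay span")
  if (stats::sd(resp) == 0) stop("constant respiration signal: subspace is rank deficient")
  resp <- resp - mean(resp)
  delays <- if (two_sided) (-max_delay):max_delay else 0:max_delay
  lo <- 1L + max(0L, max(delays))
  hi <- n + min(0L, min(delays))
  rows <- lo:hi
  V <- vapply(delays, function(d) resp[rows - d], numeric(length(rows)))
  V <- sweep(V, 2L, colMeans(V))
  attr(V, "rows") <- rows
  attr(V, "delays") <- delays
  V
}

#' Orthogonal subspace projection of HRV onto respiration
#'
#' Least-squares projection of the (centred) HRV signal onto the span of
#' the delayed-respiration subspace. The respiratory component is the
#' fitted projection, the residual component is the exact remainder, so
#' `HRV = HRV_R + HRV_perp` by construction and the two are orthogonal up
#' to numerical precision. Ill-conditioned normal equations fall back to a
#' small ridge penalty.
#'
#' @param hrv HRV signal over the stage window (numeric vector at 4 Hz,
#'   same grid as the respiration used for `V`).
#' @param V respiratory subspace from [build_resp_subspace()] (its `rows`
#'   attribute selects the aligned HRV samples), or a plain matrix with
#'   rows matching `hrv`.
#' @param ridge ridge fallback penalty, relative to the mean diagonal of
#'   the Gram matrix, used when the least-squares problem is rank
#'   deficient.
#' @param fs sampling rate of the window (Hz), kept for the spectral
#'   band powers downstream.
#' @return object of class `osp_fit`: list with `hrv` (centred, trimmed),
#'   `hrv_r` (respiratory component), `hrv_perp` (residual), `coef`
#'   (per-delay weights), `delays`, `fs`.
#' @export
osp_decompose <- function(hrv, V, ridge = 1e-8, fs = 4) {
  rows <- attr(V, "rows")
  if (!is.null(rows) && length(hrv) >= max(rows)) hrv <- hrv[rows]
  if (length(hrv) != nrow(V)) stop("hrv and V windows do not match")
  hrv <- hrv - mean(hrv)
  qrv <- qr(V)
  if (qrv$rank < ncol(V)) {
    G <- crossprod(V) + diag(ridge * mean(diag(crossprod(V))), ncol(V))
    beta <- solve(G, crossprod(V, hrv))
  } else {
    beta <- qr.coef(qrv, hrv)
  }
  hrv_r <- as.numeric(V %*% beta)
  structure(list(hrv = hrv, hrv_r = hrv_r, hrv_perp = hrv - hrv_r,
                 coef = as.numeric(beta),
                 delays = attr(V, "delays") %||% seq_len(ncol(V)) - 1L,
                 fs = fs),
            class = "osp_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.osp_fit <- function(x, ...) {
  p <- component_powers(x)
  cat(sprintf("OSP decomposition: %d samples, %d delays; P_R = %.3f, P_perp = %.3f\n",
              length(x$hrv), length(x$coef), p$p_r, p$p_perp))
  invisible(x)
}

#' @export
fitted.osp_fit <- function(object, ...) object$hrv_r

#' @export
residuals.osp_fit <- function(object, ...) object$hrv_perp

#' @export
coef.osp_fit <- function(object, ...) {
  stats::setNames(object$coef, paste0("delay", object$delays))
}

#' @export
summary.osp_fit <- function(object, ...) {
  p <- component_powers(object)
  structure(list(n = length(object$hrv), n_delays = length(object$coef),
                 powers = p), class = "summary.osp_fit")
}

#' @export
print.summary.osp_fit <- function(x, ...) {
  cat(sprintf("OSP fit on %d samples with %d delay columns\n", x$n, x$n_delays))
  cat(sprintf("  P_R = %.4f  P_perp = %.4f  P_LF_perp = %.4f  P_HF_perp = %.4f\n",
              x$powers$p_r, x$powers$p_perp, x$powers$p_lf_perp,
              x$powers$p_hf_perp))
  invisible(x)
}

#' Frequency-domain HRV parameters from an OSP decomposition
#'
#' Relative powers of the respiratory and residual components
#' (`P_R + P_perp = 1` by the Pythagorean identity of the orthogonal
#' split), and the LF (0.04-0.15 Hz) and HF (0.15-0.4 Hz) band powers of
#' the residual component from its Welch spectrum, normalised by the total
#' HRV power (`normalize = "total"`) or by the residual power
#' (`normalize = "residual"`).
#'
#' @param fit an `osp_fit` from [osp_decompose()].
#' @param lf,hf band edges in Hz.
#' @param normalize normalisation of the residual band powers.
#' @return data.frame with `p_r`, `p_perp`, `p_lf_perp`, `p_hf_perp`
#'   (arbitrary units), `defined`.
#' @export
component_powers <- function(fit, lf = c(0.04, 0.15), hf = c(0.15, 0.4),
                             normalize = c("total", "residual")) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(fit, "osp_fit"))
  tot <- mean(fit$hrv^2)
  if (tot <= 0) {
    return(data.frame(p_r = NA_real_, p_perp = NA_real_, p_lf_perp = NA_real_,
                      p_hf_perp = NA_real_, defined = FALSE))
  }
  p_r <- mean(fit$hrv_r^2) / tot
  p_perp <- mean(fit$hrv_perp^2) / tot
  res_pow <- mean(fit$hrv_perp^2)
  if (res_pow > 0) {
    sp <- welch_psd(fit$hrv_perp, fit$fs, seg_len = min(60, length(fit$hrv_perp) / fit$fs / 2))
    denom <- if (normalize == "total") tot else res_pow
    p_lf <- band_power(sp, lf[1], lf[2]) / denom
    p_hf <- band_power(sp, hf[1], hf[2]) / denom
  } else {
    p_lf <- 0; p_hf <- 0
  }
  data.frame(p_r = p_r, p_perp = p_perp, p_lf_perp = p_lf, p_hf_perp = p_hf,
             defined = TRUE)
}
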