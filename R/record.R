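#' Multi-lead ECG record
#'
#' Container for a sampled multi-lead ECG with stage annotations.
#'
#' @param leads numeric matrix, one column per lead, in mV.
#' @param fs sampling frequency in Hz (> 0).
#' @param stage_annotations data.frame with columns `stage`, `t_start`,
#'   `t_end` (seconds); stages must not overlap.
#' @param subject_id optional integer.
#' @return object of class `ecg_record`.
#' @export
ecg_record <- function(leads, fs, stage_annotations = NULL, subject_id = NA_integer_) {
  leads <- as.matrix(leads)
  stopifnot(is.numeric(leads), fs > 0)
  if (!is.null(stage_annotations)) {
    stopifnot(all(c("stage", "t_start", "t_end") %in% names(stage_annotations)))
    sa <- stage_annotations[order(stage_annotations$t_start), , drop = FALSE]
    if (nrow(sa) > 1L && any(sa$t_start[-1L] < sa$t_end[-nrow(sa)] - 1e-9)) {
      stop("stage annotations overlap")
    }
  }
  structure(list(leads = leads, fs = fs,
                 stage_annotations = stage_annotations,
                 subject_id = subject_id),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("ECG record: %d leads, %.1f s at %g Hz", ncol(x$leads),
              (nrow(x$leads) - 1L) / x$fs, x$fs))
  if (!is.na(x$subject_id)) cat(", subject", x$subject_id)
  cat("\n")
  if (!is.null(x$stage_annotations)) {
    cat("  stages:", paste(sprintf("%s [%g, %g]", x$stage_annotations$stage,
                                   x$stage_annotations$t_start,
                                   x$stage_annotations$t_end), collapse = "  "), "\n")
  }
  invisible(x)
}

#' Write / read an ECG record as delimited text
#'
#' The signal file holds `time` plus one column per lead (tab-separated);
#' stage annotations go to a companion `<path>.stages` file.
#'
#' @param record an [ecg_record()].
#' @param path file path.
#' @export
write_ecg_record <- function(record, path) {
  df <- data.frame(time = (seq_len(nrow(record$leads)) - 1L) / record$fs,
                   record$leads)
  names(df) <- c("time", paste0("lead", seq_len(ncol(record$leads))))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(record$stage_annotations)) {
    utils::write.table(record$stage_annotations, paste0(path, ".stages"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_ecg_record
#' @param subject_id optional integer attached to the record read back.
#' @return [read_ecg_record()] returns an [ecg_record()]; the sampling rate
#'   is recovered from the time column.
#' @export
read_ecg_record <- function(path, subject_id = NA_integer_) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  fs <- 1 / stats::median(diff(df$time))
  sa <- NULL
  spath <- paste0(path, ".stages")
  if (file.exists(spath)) {
    sa <- utils::read.table(spath, header = TRUE, sep = "\t",
                            colClasses = c("character", "numeric", "numeric"))
  }
  ecg_record(as.matrix(df[, -1L, drop = FALSE]), fs = fs,
             stage_annotations = sa, subject_id = subject_id)
}

#' Remove baseline wander
#'
#' Estimates the sub-0.03 Hz baseline of every lead with a zero-phase
#' low-pass filter and subtracts it, leaving the cardiac content untouched.
#'
#' @param record an [ecg_record()].
#' @param cutoff baseline cut-off frequency in Hz.
#' @return the record with baseline-free leads.
#' @export
remove_baseline <- function(record, cutoff = 0.03) {
  stopifnot(inherits(record, "ecg_record"))
  n <- nrow(record$leads)
  if (n < 2 * record$fs / cutoff) {
    stop("record shorter than twice the baseline filter memory")
  }
  for (l in seq_len(ncol(record$leads))) {
    record$leads[, l] <- record$leads[, l] -
      lowpass_trend(record$leads[, l], record$fs, cutoff)
  }
  record
}
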