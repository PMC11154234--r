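#' Anomalous-subject scan by misclassification accumulation
#'
#' Pools the per-case correctness of every classifier cell (family x
#' feature count x class) from one or more tasks, keeps only cells whose
#' accuracy strictly exceeds the precision threshold, and counts how often
#' each subject is misclassified across the qualifying cells. With the
#' full grid (2 classes x 4 families x 9 feature counts) a subject has 72
#' result slots per two-class task. Subjects whose count exceeds
#' `flag_count` are flagged as responding anomalously.
#'
#' @param sweeps a `classifier_sweep`, or a list of them (their cases are
#'   pooled).
#' @param threshold precision threshold in percent; cells with accuracy
#'   strictly above it qualify.
#' @param flag_count flag subjects misclassified more than this many times
#'   across the qualifying cells.
#' @return object of class `anomaly_report`: list with `counts`
#'   (data.frame `subject`, `n_misclassified`, `n_slots`), `flagged`
#'   (subject ids), `n_qualifying_cells`, `threshold`, `flag_count`.
#' @export
anomaly_scan <- function(sweeps, threshold = 70, flag_count = 20) {
  if (inherits(sweeps, "classifier_sweep")) sweeps <- list(sweeps)
  cases <- do.call(rbind, lapply(sweeps, `[[`, "cases"))
  qual <- cases[cases$accuracy > threshold, , drop = FALSE]
  n_cells <- if (nrow(qual)) {
    nrow(unique(qual[, c("task", "family", "n_features")]))
  } else 0L
  if (n_cells == 0L) {
    warning("no classifier cell exceeds the precision threshold")
    subs <- sort(unique(cases$subject))
    counts <- data.frame(subject = subs, n_misclassified = 0L, n_slots = 0L)
    return(structure(list(counts = counts, flagged = integer(0),
                          n_qualifying_cells = 0L, threshold = threshold,
                          flag_count = flag_count),
                     class = "anomaly_report"))
  }
  agg <- stats::aggregate(cbind(n_misclassified = !qual$correct,
                                n_slots = rep(1L, nrow(qual))) ~ subject,
                          data = qual, FUN = sum)
  # subjects never appearing in a qualifying cell still get a zero row
  all_subs <- sort(unique(cases$subject))
  missing <- setdiff(all_subs, agg$subject)
  if (length(missing)) {
    agg <- rbind(agg, data.frame(subject = missing, n_misclassified = 0L,
                                 n_slots = 0L))
  }
  agg <- agg[order(-agg$n_misclassified, agg$subject), ]
  rownames(agg) <- NULL
  structure(list(counts = agg,
                 flagged = agg$subject[agg$n_misclassified > flag_count],
                 n_qualifying_cells = n_cells, threshold = threshold,
                 flag_count = flag_count),
            class = "anomaly_report")
}

#' @export
print.anomaly_report <- function(x, ...) {
  cat(sprintf("Anomaly scan: %d qualifying cells (accuracy > %g%%)\n",
              x$n_qualifying_cells, x$threshold))
  top <- utils::head(x$counts, 8)
  cat("  top misclassification counts:",
      paste(sprintf("s%d:%d", top$subject, top$n_misclassified),
            collapse = "  "), "\n")
  if (length(x$flagged)) {
    cat("  flagged (>", x$flag_count, "):",
        paste(x$flagged, collapse = ", "), "\n")
  } else {
    cat("  no subject exceeds the flag count\n")
  }
  invisible(x)
}

#' @export
summary.anomaly_report <- function(object, ...) {
  cat(sprintf("Qualifying cells: %d; flag threshold: > %d misclassifications\n",
              object$n_qualifying_cells, object$flag_count))
  print(object$counts)
  invisible(object)
}
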