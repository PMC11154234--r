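#' Relative change of a parameter against the baseline stage
#'
#' `R(Y_S) = (Y_S - Y_1D) / (Y_S + Y_1D)`: a dimensionless, bounded
#' contrast that cancels inter-subject scale. For non-negative parameters
#' it lies in \[-1, 1\]; it is antisymmetric under swapping the two
#' arguments. A vanishing denominator yields `NA` with a warning.
#'
#' @param y_s parameter value at the evaluated stage.
#' @param y_ref parameter value at the reference (baseline) stage.
#' @return relative change, same length as the inputs.
#' @export
relative_change <- function(y_s, y_ref) {
  den <- y_s + y_ref
  bad <- !is.na(den) & den == 0
  if (any(bad)) warning("zero denominator in relative change: NA returned")
  ifelse(bad, NA_real_, (y_s - y_ref) / den)
}

#' Paired stage-vs-baseline tests with a normality gate
#'
#' For each stage's sample of relative changes, a Shapiro-Wilk test at
#' `alpha_norm` decides between the paired Student t test and the Wilcoxon
#' signed-rank test of the changes against zero (change versus the
#' baseline stage). Significance is starred at 0.05, 0.01 and 0.001.
#'
#' @param ratios numeric vector (one stage) or a list/data.frame of
#'   vectors, one per stage, of per-subject relative changes.
#' @param alpha_norm normality-gate level.
#' @return data.frame with `stage`, `n`, `test` (`"t"` or `"wilcoxon"`),
#'   `p_value`, `stars` (`""`, `"*"`, `"**"`, `"***"`).
#' @export
paired_stage_tests <- function(ratios, alpha_norm = 0.05) {
  if (is.numeric(ratios)) ratios <- list(ratio = ratios)
  out <- lapply(names(ratios), function(s) {
    x <- ratios[[s]]
    x <- x[!is.na(x)]
    n <- length(x)
    if (n < 6L) stop("need at least 6 paired observations (stage ", s, ")")
    if (stats::sd(x) == 0) {
      # degenerate sample: all ties; the signed-rank branch with no
      # information -> p = 1
      return(data.frame(stage = s, n = n, test = "wilcoxon", p_value = 1,
                        normal = FALSE, stars = ""))
    }
    normal <- stats::shapiro.test(x)$p.value >= alpha_norm
    p <- if (normal) {
      stats::t.test(x, mu = 0)$p.value
    } else {
      suppressWarnings(stats::wilcox.test(x, mu = 0, exact = FALSE)$p.value)
    }
    data.frame(stage = s, n = n, test = if (normal) "t" else "wilcoxon",
               p_value = p, normal = normal,
               stars = if (p < 0.001) "***" else if (p < 0.01) "**"
                       else if (p < 0.05) "*" else "")
  })
  do.call(rbind, out)
}

#' Repeated-measures comparison across the four non-baseline stages
#'
#' Omnibus test over the per-subject relative changes of the stages
#' 3D, 5, 3A, 1A: repeated-measures ANOVA when every stage sample passes
#' the Shapiro-Wilk gate, otherwise a Friedman test. Pairwise follow-up
#' uses paired t or Wilcoxon tests (same gate, per pair) with Bonferroni
#' correction over the 6 stage pairs; the arrow set lists the significant
#' ordered pairs (higher median first). Subjects missing any stage are
#' dropped.
#'
#' @param ratios data.frame or named list: one numeric vector of
#'   per-subject relative changes per stage (equal subject order).
#' @param alpha significance level after correction.
#' @param alpha_norm normality-gate level.
#' @return list with `omnibus` (`test`, `p_value`), `pairwise`
#'   (data.frame: `stage_a`, `stage_b`, `p_raw`, `p_adj`, `significant`,
#'   `direction`), `n_complete`.
#' @export
multi_stage_comparison <- function(ratios, alpha = 0.05, alpha_norm = 0.05) {
  m <- as.matrix(as.data.frame(ratios, check.names = FALSE))
  complete <- stats::complete.cases(m)
  m <- m[complete, , drop = FALSE]
  n <- nrow(m)
  if (n < 6L) stop("need at least 6 complete cases")
  stages <- colnames(m)
  normal_all <- all(vapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    stats::sd(x) > 0 && stats::shapiro.test(x)$p.value >= alpha_norm
  }, logical(1)))
  if (normal_all) {
    long <- data.frame(y = as.vector(m),
                       stage = factor(rep(stages, each = n)),
                       subject = factor(rep(seq_len(n), times = ncol(m))))
    fit <- stats::aov(y ~ stage + Error(subject), data = long)
    p_omni <- summary(fit)[["Error: Within"]][[1]][["Pr(>F)"]][1]
    omni_test <- "anova"
  } else {
    p_omni <- stats::friedman.test(m)$p.value
    omni_test <- "friedman"
  }
  pairs <- utils::combn(stages, 2)
  pw <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    d <- m[, a] - m[, b]
    use_t <- stats::sd(d) > 0 && stats::shapiro.test(d)$p.value >= alpha_norm
    p <- if (stats::sd(d) == 0) 1
         else if (use_t) stats::t.test(d, mu = 0)$p.value
         else suppressWarnings(stats::wilcox.test(d, mu = 0, exact = FALSE)$p.value)
    data.frame(stage_a = a, stage_b = b, p_raw = p)
  })
  pw <- do.call(rbind, pw)
  pw$p_adj <- pmin(1, pw$p_raw * nrow(pw))  # Bonferroni over the 6 pairs
  pw$significant <- pw$p_adj < alpha
  med <- apply(m, 2, stats::median)
  pw$direction <- ifelse(!pw$significant, "",
                         ifelse(med[pw$stage_a] >= med[pw$stage_b],
                                paste(pw$stage_a, ">", pw$stage_b),
                                paste(pw$stage_b, ">", pw$stage_a)))
  list(omnibus = data.frame(test = omni_test, p_value = p_omni),
       pairwise = pw, n_complete = n)
}
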