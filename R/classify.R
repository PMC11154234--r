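#' The nine stage-relative HRV features
#'
#' Column names of the feature set used for stage classification: fused
#' respiratory rate, the four time-domain and the four OSP frequency-domain
#' parameters, each as a relative change against stage 1D.
#' @export
hrv_feature_names <- function() {
  c("f_r", "nn_med", "iqr_nn", "rmssd", "pnn50",
    "p_r", "p_perp", "p_lf_perp", "p_hf_perp")
}

#' Define a stage-identification task
#'
#' Builds the sample matrix for one set of classes from a stage-relative
#' feature table: each eligible subject contributes one feature vector per
#' member stage, labelled by its class (stages 3D and 3A merge into class
#' "3DA" in the three-class task). Subjects missing any member stage, or
#' with incomplete features there, are excluded.
#'
#' @param features data.frame with columns `subject`, `stage` and the
#'   columns of [hrv_feature_names()] (relative changes).
#' @param stages member stages, e.g. `c("5", "3A")`.
#' @param name task name; defaults to `C.<stages>` in the study's naming.
#' @param merge_3d3a merge stages 3D and 3A into one class (three-class
#'   task).
#' @return object of class `class_task`: list with `x` (matrix), `y`
#'   (factor of class labels), `subject`, `stage`, `name`, `subjects`
#'   (eligible ids).
#' @export
class_task <- function(features, stages, name = NULL, merge_3d3a = FALSE) {
  feat_cols <- hrv_feature_names()
  stopifnot(all(c("subject", "stage", feat_cols) %in% names(features)))
  rows <- features[features$stage %in% stages, , drop = FALSE]
  ok_row <- stats::complete.cases(rows[, feat_cols])
  rows <- rows[ok_row, , drop = FALSE]
  counts <- table(rows$subject)
  eligible <- as.integer(names(counts))[counts == length(stages)]
  rows <- rows[rows$subject %in% eligible, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no eligible subjects for task")
  cls <- rows$stage
  if (merge_3d3a) cls[cls %in% c("3D", "3A")] <- "3DA"
  if (is.null(name)) {
    name <- paste0("C.", paste(unique(cls), collapse = "-"))
  }
  structure(list(x = as.matrix(rows[, feat_cols]),
                 y = factor(cls), subject = rows$subject,
                 stage = rows$stage, name = name,
                 subjects = sort(eligible)),
            class = "class_task")
}

#' @export
print.class_task <- function(x, ...) {
  cat(sprintf("Task %s: %d subjects, %d samples, classes %s\n", x$name,
              length(x$subjects), nrow(x$x),
              paste(levels(x$y), collapse = "/")))
  invisible(x)
}

#' The standard two-class task set of the hyperbaric protocol
#'
#' Sequential 2 atm and 4 atm pressure contrasts: C.3D-5, C.5-3A, C.5-1A
#' and C.3A-1A (3D vs 3A is excluded: same pressure).
#' @param features stage-relative feature table, see [class_task()].
#' @return named list of `class_task` objects.
#' @export
standard_tasks <- function(features) {
  defs <- list(`C.3D-5` = c("3D", "5"), `C.5-3A` = c("5", "3A"),
               `C.5-1A` = c("5", "1A"), `C.3A-1A` = c("3A", "1A"))
  lapply(names(defs), function(nm) class_task(features, defs[[nm]], name = nm)) |>
    stats::setNames(names(defs))
}

#' Classification accuracy in percent
#'
#' `100 * (TP + TN) / total cases`; each eligible subject contributes one
#' case per class of the task.
#'
#' @param correct logical vector of per-case correctness, or the number of
#'   correct cases when `total` is given.
#' @param total optional total case count.
#' @return accuracy in percent.
#' @export
accuracy_pct <- function(correct, total = NULL) {
  if (is.null(total)) {
    if (length(correct) == 0L) stop("accuracy undefined with zero cases")
    100 * mean(correct)
  } else {
    if (total == 0) stop("accuracy undefined with zero cases")
    100 * correct / total
  }
}

# minimal pooled-covariance linear discriminant (used inside the subspace
# ensemble; cross-checked against MASS::lda in the tests)
pooled_lda_fit <- function(x, y) {
  x <- as.matrix(x)
  classes <- levels(y)
  mu <- do.call(rbind, lapply(classes, function(c) {
    colMeans(x[y == c, , drop = FALSE])
  }))
  centred <- x - mu[as.integer(y), , drop = FALSE]
  sp <- crossprod(centred) / max(1L, nrow(x) - length(classes))
  sp <- sp + diag(1e-8 * (mean(diag(sp)) + 1e-12), ncol(x))
  prior <- as.numeric(table(y)[classes]) / length(y)
  list(mu = mu, sinv = solve(sp), prior = prior, classes = classes)
}

pooled_lda_predict <- function(fit, x) {
  x <- as.matrix(x)
  scores <- vapply(seq_along(fit$classes), function(c) {
    m <- fit$mu[c, ]
    as.numeric(x %*% (fit$sinv %*% m)) - 0.5 * sum(m * (fit$sinv %*% m)) +
      log(fit$prior[c])
  }, numeric(nrow(x)))
  scores <- matrix(scores, nrow = nrow(x))
  fit$classes[max.col(scores, ties.method = "first")]
}

cosine_knn_predict <- function(xtr, ytr, xte, k = 10) {
  k <- min(k, nrow(xtr))
  eps <- 1e-12
  ntr <- sqrt(rowSums(xtr^2)) + eps
  nte <- sqrt(rowSums(xte^2)) + eps
  sim <- (xte %*% t(xtr)) / outer(nte, ntr)
  classes <- levels(ytr)
  pred <- character(nrow(xte))
  for (i in seq_len(nrow(xte))) {
    d <- 1 - sim[i, ]
    nb <- order(d)[seq_len(k)]
    votes <- table(factor(ytr[nb], levels = classes))
    best <- which(votes == max(votes))
    if (length(best) > 1L) {
      # tie: smallest mean distance to the tied class's neighbours
      md <- vapply(classes[best], function(c) mean(d[nb][ytr[nb] == c]),
                   numeric(1))
      best <- best[which.min(md)]
    }
    pred[i] <- classes[best]
  }
  pred
}

subspace_ensemble_predict <- function(xtr, ytr, xte, n_learners = 30,
                                      dim = NULL, seed = 1L) {
  p <- ncol(xtr)
  if (is.null(dim)) dim <- ceiling(p / 2)
  dim <- min(dim, p)
  classes <- levels(ytr)
  votes <- matrix(0, nrow(xte), length(classes))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  subsets <- replicate(n_learners, sort(sample.int(p, dim)), simplify = FALSE)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  for (s in subsets) {
    fit <- pooled_lda_fit(xtr[, s, drop = FALSE], ytr)
    pr <- pooled_lda_predict(fit, xte[, s, drop = FALSE])
    idx <- cbind(seq_len(nrow(xte)), match(pr, classes))
    votes[idx] <- votes[idx] + 1
  }
  classes[max.col(votes, ties.method = "first")]
}

#' The four classifier families
#'
#' `"lda"`: linear discriminant analysis with pooled covariance
#' (MASS::lda). `"svm"`: Gaussian-kernel support vector machine with
#' kernel scale `sqrt(p)` for `p` features (gamma = 1/p) and box
#' constraint 1 (e1071::svm). `"knn"`: k-nearest neighbours with cosine
#' distance, k = 10. `"dec"`: discriminant ensemble - random-subspace
#' ensemble of 30 pooled-covariance linear discriminants on
#' `ceiling(p/2)`-dimensional subspaces, majority vote.
#' @export
classifier_families <- function() c("lda", "svm", "knn", "dec")

train_predict <- function(family, xtr, ytr, xte, seed = 1L) {
  ytr <- droplevels(factor(ytr))
  if (nlevels(ytr) < 2L) return(rep(levels(ytr)[1], nrow(xte)))
  pred <- switch(
    family,
    lda = tryCatch({
      fit <- MASS::lda(xtr, grouping = ytr)
      as.character(stats::predict(fit, xte)$class)
    }, error = function(e) {
      as.character(pooled_lda_predict(pooled_lda_fit(xtr, ytr), xte))
    }),
    svm = {
      fit <- e1071::svm(xtr, ytr, kernel = "radial",
                        gamma = 1 / ncol(xtr), cost = 1, scale = FALSE)
      as.character(stats::predict(fit, xte))
    },
    knn = cosine_knn_predict(xtr, ytr, xte),
    dec = subspace_ensemble_predict(xtr, ytr, xte, seed = seed),
    stop("unknown classifier family ", family)
  )
  pred
}

#' Leave-one-subject-out evaluation of one classifier cell
#'
#' Holds out one subject at a time: the classifier trains on every other
#' subject's samples (features z-scored with the training fold's
#' statistics) and predicts all of the held-out subject's stage samples.
#' Returns per-case correctness and the aggregated accuracy.
#'
#' @param task a [class_task()].
#' @param family one of [classifier_families()].
#' @param feature_set feature names (subset of [hrv_feature_names()]) or
#'   column indices.
#' @param seed integer seed (used by the stochastic ensemble family).
#' @return list with `accuracy` (%), `cases` (data.frame `subject`,
#'   `stage`, `class`, `predicted`, `correct`), `family`, `n_features`.
#' @export
loo_evaluate <- function(task, family, feature_set = hrv_feature_names(),
                         seed = 1L) {
  stopifnot(inherits(task, "class_task"))
  x <- task$x[, feature_set, drop = FALSE]
  cases <- vector("list", length(task$subjects))
  for (i in seq_along(task$subjects)) {
    s <- task$subjects[i]
    te <- task$subject == s
    tr <- !te
    stopifnot(!any(task$subject[tr] == s))  # leakage canary
    mu <- colMeans(x[tr, , drop = FALSE])
    sg <- apply(x[tr, , drop = FALSE], 2, stats::sd)
    sg[sg == 0 | is.na(sg)] <- 1
    xtr <- sweep(sweep(x[tr, , drop = FALSE], 2, mu), 2, sg, "/")
    xte <- sweep(sweep(x[te, , drop = FALSE], 2, mu), 2, sg, "/")
    pred <- train_predict(family, xtr, task$y[tr], xte, seed = seed)
    cases[[i]] <- data.frame(subject = s, stage = task$stage[te],
                             class = as.character(task$y[te]),
                             predicted = pred,
                             correct = pred == as.character(task$y[te]))
  }
  cases <- do.call(rbind, cases)
  list(accuracy = accuracy_pct(cases$correct), cases = cases,
       family = family, n_features = ncol(x))
}

#' Greedy wrapper feature selection
#'
#' Forward selection over the nine features: at each step every remaining
#' feature is appended to the selected set and evaluated by
#' [loo_evaluate()]; the feature with the highest accuracy joins the set,
#' ties broken uniformly at random under the given seed. Returns the full
#' selection order, the nine-point accuracy curve, and the per-case
#' correctness of every curve cell (feeding the anomaly scan).
#'
#' @inheritParams loo_evaluate
#' @param max_features stop after this many features (default all nine).
#' @return object of class `wrapper_result`: list with `order` (features in
#'   selection order), `curve` (data.frame `n_features`, `feature`,
#'   `accuracy`), `cells` (list of [loo_evaluate()] results per count),
#'   `family`, `task`.
#' @export
wrapper_select <- function(task, family, seed = 1L,
                           max_features = length(hrv_feature_names())) {
  feats <- colnames(task$x)
  selected <- character(0)
  curve <- list(); cells <- list()
  rng <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    st <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    st
  })
  for (step in seq_len(min(max_features, length(feats)))) {
    remaining <- setdiff(feats, selected)
    evals <- lapply(remaining, function(f) {
      loo_evaluate(task, family, c(selected, f), seed = seed)
    })
    acc <- vapply(evals, `[[`, numeric(1), "accuracy")
    best <- which(acc == max(acc))
    if (length(best) > 1L) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", rng, envir = globalenv())
      best <- sample(best, 1L)
      rng <- get(".Random.seed", globalenv())
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    } else {
      best <- best[1L]
    }
    selected <- c(selected, remaining[best])
    curve[[step]] <- data.frame(n_features = step, feature = remaining[best],
                                accuracy = acc[best])
    cells[[step]] <- evals[[best]]
  }
  structure(list(order = selected, curve = do.call(rbind, curve),
                 cells = cells, family = family, task = task$name),
            class = "wrapper_result")
}

#' @export
print.wrapper_result <- function(x, ...) {
  cat(sprintf("Wrapper selection (%s, %s):\n", x$task, x$family))
  cat("  order:", paste(x$order, collapse = " > "), "\n")
  cat("  accuracy (%):", paste(sprintf("%.1f", x$curve$accuracy), collapse = " "), "\n")
  invisible(x)
}

#' Full classifier sweep over families and feature counts
#'
#' Runs [wrapper_select()] for every classifier family on one task,
#' producing the complete grid of (family, feature count) cells that the
#' anomaly scan accumulates over.
#'
#' @inheritParams loo_evaluate
#' @param families classifier families to include.
#' @return object of class `classifier_sweep`: list with `results`
#'   (data.frame `task`, `family`, `n_features`, `accuracy`), `cases`
#'   (data.frame of per-case correctness for every cell), `wrappers`.
#' @export
classifier_sweep <- function(task, families = classifier_families(),
                             seed = 1L) {
  res <- list(); cas <- list(); wr <- list()
  for (fam in families) {
    w <- wrapper_select(task, fam, seed = seed)
    wr[[fam]] <- w
    for (i in seq_along(w$cells)) {
      cell <- w$cells[[i]]
      res[[length(res) + 1L]] <- data.frame(task = task$name, family = fam,
                                            n_features = i,
                                            accuracy = cell$accuracy)
      cc <- cell$cases
      cc$task <- task$name; cc$family <- fam; cc$n_features <- i
      cc$accuracy <- cell$accuracy
      cas[[length(cas) + 1L]] <- cc
    }
  }
  structure(list(results = do.call(rbind, res), cases = do.call(rbind, cas),
                 wrappers = wr, task = task$name),
            class = "classifier_sweep")
}

#' @export
print.classifier_sweep <- function(x, ...) {
  cat("Classifier sweep on", x$task, "\n")
  best <- x$results[which.max(x$results$accuracy), ]
  cat(sprintf("  best cell: %s with %d features, %.1f%%\n", best$family,
              best$n_features, best$accuracy))
  invisible(x)
}
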