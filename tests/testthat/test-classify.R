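test_that("accuracy bookkeeping matches the TP+TN definition", {
  expect_equal(accuracy_pct(rep(TRUE, 10)), 100)
  expect_equal(round(accuracy_pct(52 - 6, 52), 1), 88.5)
  expect_equal(round(accuracy_pct(54 - 10, 54), 1), 81.5)
  expect_error(accuracy_pct(logical(0)), "zero cases")
  expect_error(accuracy_pct(0, 0), "zero cases")
})

test_that("task construction applies stage eligibility rules", {
  feats <- make_feature_table(n_subjects = 10, d = 2)
  # subject 4 loses its "5" row -> ineligible
  feats <- feats[!(feats$subject == 4 & feats$stage == "5"), ]
  task <- class_task(feats, c("5", "3A"))
  expect_false(4 %in% task$subjects)
  expect_equal(nrow(task$x), 9 * 2)
  expect_equal(as.character(sort(unique(task$y))), c("3A", "5"))
})

test_that("a perfectly separating feature yields 100% for every family", {
  feats <- make_feature_table(n_subjects = 12, d = 40, seed = 2)
  task <- class_task(feats, c("5", "3A"))
  for (fam in classifier_families()) {
    out <- loo_evaluate(task, fam, "f_r", seed = 3)
    expect_equal(out$accuracy, 100, info = fam)
  }
})

test_that("uninformative features give chance-level accuracy", {
  set.seed(61)
  accs <- replicate(150, {
    feats <- make_feature_table(n_subjects = 14, d = 0,
                                seed = sample.int(1e6, 1))
    task <- class_task(feats, c("5", "3A"))
    loo_evaluate(task, "lda", "f_r")$accuracy
  })
  expect_lt(abs(mean(accs) - 50), 5)
})

test_that("LDA accuracy approaches the Gaussian Bayes rate", {
  # one feature, classes N(+-d/2, 1), d = 1: Bayes accuracy = pnorm(d/2)
  set.seed(62)
  accs <- replicate(25, {
    feats <- make_feature_table(n_subjects = 40, d = 1,
                                seed = sample.int(1e6, 1))
    task <- class_task(feats, c("5", "3A"))
    loo_evaluate(task, "lda", "f_r")$accuracy
  })
  bayes <- 100 * stats::pnorm(0.5)
  expect_lt(abs(mean(accs) - bayes), 10)
})

test_that("the ensemble's internal discriminant matches MASS::lda", {
  set.seed(63)
  x <- rbind(matrix(stats::rnorm(60, 0), ncol = 3),
             matrix(stats::rnorm(60, 1.5), ncol = 3))
  y <- factor(rep(c("a", "b"), each = 20))
  xt <- matrix(stats::rnorm(150, 0.75), ncol = 3)
  mine <- hyperhrv:::pooled_lda_predict(hyperhrv:::pooled_lda_fit(x, y), xt)
  mass <- as.character(stats::predict(MASS::lda(x, grouping = y), xt)$class)
  expect_equal(mine, mass)
})

test_that("cosine KNN votes by angular proximity", {
  xtr <- rbind(matrix(rep(c(1, 0.1), 12), ncol = 2, byrow = TRUE) *
                 stats::runif(12, 0.5, 2),
               matrix(rep(c(0.1, 1), 12), ncol = 2, byrow = TRUE) *
                 stats::runif(12, 0.5, 2))
  ytr <- factor(rep(c("a", "b"), each = 12))
  xte <- rbind(c(5, 0.4), c(0.2, 3))  # norms differ, directions decide
  pred <- hyperhrv:::cosine_knn_predict(xtr, ytr, xte, k = 10)
  expect_equal(pred, c("a", "b"))
})

test_that("greedy selection starts from the single best feature", {
  feats <- make_feature_table(n_subjects = 12, d = 30, seed = 4)
  task <- class_task(feats, c("5", "3A"))
  w <- wrapper_select(task, "lda", seed = 5, max_features = 3)
  expect_equal(w$order[1], "f_r")
  expect_equal(w$curve$accuracy[1], 100)
})

test_that("step-2 greedy choice equals the exhaustive pair search", {
  set.seed(65)
  for (rep in 1:5) {
    feats <- make_feature_table(n_subjects = 10, d = 1.2,
                                seed = sample.int(1e6, 1))
    task <- class_task(feats, c("5", "3A"))
    w <- wrapper_select(task, "lda", seed = 6, max_features = 2)
    f1 <- w$order[1]
    pair_acc <- vapply(setdiff(hrv_feature_names(), f1), function(f) {
      loo_evaluate(task, "lda", c(f1, f))$accuracy
    }, numeric(1))
    expect_equal(w$curve$accuracy[2], max(pair_acc))
  }
})

test_that("duplicate features tie-break reproducibly without changing accuracy", {
  feats <- make_feature_table(n_subjects = 12, d = 3, seed = 7)
  feats$nn_med <- feats$f_r  # exact duplicate of the informative feature
  task <- class_task(feats, c("5", "3A"))
  # duplicated columns make MASS::lda warn about collinearity, by design
  w1 <- suppressWarnings(wrapper_select(task, "lda", seed = 8, max_features = 2))
  w2 <- suppressWarnings(wrapper_select(task, "lda", seed = 8, max_features = 2))
  expect_identical(w1$order, w2$order)
  expect_true(w1$order[1] %in% c("f_r", "nn_med"))
  w3 <- suppressWarnings(wrapper_select(task, "lda", seed = 99, max_features = 2))
  expect_equal(w1$curve$accuracy, w3$curve$accuracy)
})

test_that("the three-class task merges the two 3 atm stages", {
  feats <- make_feature_table(n_subjects = 8, d = 1, seed = 9)
  extra <- lapply(c("3D", "1A"), function(st) {
    e <- feats[feats$stage == "5", ]
    e$stage <- st
    e[, hrv_feature_names()] <- e[, hrv_feature_names()] + stats::rnorm(nrow(e))
    e
  })
  feats4 <- rbind(feats, do.call(rbind, extra))
  task <- class_task(feats4, c("3D", "5", "3A", "1A"), merge_3d3a = TRUE)
  expect_setequal(levels(task$y), c("3DA", "5", "1A"))
  expect_equal(sum(task$y == "3DA"), 2 * 8)
  out <- loo_evaluate(task, "lda")
  expect_true(out$accuracy >= 0 && out$accuracy <= 100)
})

test_that("anomaly counting pools only cells strictly above threshold", {
  # constructed case grid: 2 subjects x 2 cells, one cell exactly at 70%
  mk_cases <- function(acc, fam, nf, correct) {
    data.frame(subject = c(1, 1, 2, 2), stage = c("5", "1A", "5", "1A"),
               class = c("5", "1A", "5", "1A"),
               predicted = "x", correct = correct,
               task = "C.5-1A", family = fam, n_features = nf, accuracy = acc)
  }
  sweep_obj <- list(cases = rbind(
    mk_cases(70.0, "lda", 1, c(TRUE, TRUE, FALSE, FALSE)),   # boundary: out
    mk_cases(75.0, "knn", 1, c(TRUE, FALSE, TRUE, TRUE))))
  rep <- anomaly_scan(list(sweep_obj), flag_count = 0)
  expect_equal(rep$n_qualifying_cells, 1)
  counts <- rep$counts
  expect_equal(counts$n_misclassified[counts$subject == 1], 1)
  expect_equal(counts$n_misclassified[counts$subject == 2], 0)
  expect_equal(rep$flagged, 1)
  empty <- suppressWarnings(anomaly_scan(list(list(cases = mk_cases(
    60, "lda", 1, rep(TRUE, 4)))), flag_count = 0))
  expect_equal(empty$n_qualifying_cells, 0)
})
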