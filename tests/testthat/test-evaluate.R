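test_that("segment metrics evaluate the printed formulas", {
  m <- segment_metrics(list(tp = 5, tn = 5, fp = 0, fn = 0))
  expect_equal(unname(m), c(1, 1, 1))
  m2 <- segment_metrics(list(tp = 3, tn = 4, fp = 1, fn = 2))
  expect_equal(unname(m2["specificity"]), 0.8)
  expect_equal(unname(m2["sensitivity"]), 0.6)
  expect_equal(unname(m2["accuracy"]), 0.7)
  # degenerate all-negative predictor on balanced data
  truth <- rep(c("A", "N"), each = 5)
  pred <- rep("N", 10)
  m3 <- segment_metrics(confusion_counts(truth, pred))
  expect_equal(unname(m3), c(1, 0, 0.5))
  # zero denominators flag the metric as undefined, without crashing
  expect_warning(m4 <- segment_metrics(list(tp = 0, tn = 3, fp = 1, fn = 0)),
                 "sensitivity undefined")
  expect_true(is.na(m4["sensitivity"]))
})

test_that("accuracy decomposes as the class-prevalence-weighted Sn/Sp mix", {
  set.seed(3)
  for (i in 1:15) {
    truth <- sample(c("A", "N"), 60, replace = TRUE, prob = c(0.4, 0.6))
    pred <- ifelse(runif(60) < 0.7, truth, sample(c("A", "N"), 60,
                                                  replace = TRUE))
    cc <- confusion_counts(truth, pred)
    m <- suppressWarnings(segment_metrics(cc))
    p <- sum(truth == "A")
    n <- sum(truth == "N")
    if (p > 0 && n > 0) {
      expect_equal(unname(m["accuracy"]),
                   unname((m["sensitivity"] * p + m["specificity"] * n) /
                            (p + n)))
    }
  }
})

test_that("ROC AUC equals the exhaustive concordant-pair fraction", {
  # perfectly ordered scores
  expect_equal(roc_auc(c("N", "N", "A", "A"), c(0.1, 0.2, 0.8, 0.9)), 1.0)
  # random fixtures up to n = 50, including ties
  set.seed(29)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    y <- sample(c("A", "N"), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c("A", "N")
    scores <- round(runif(n), sample(c(1, 2, 8), 1))  # coarse rounding => ties
    expect_equal(roc_auc(y, scores), pairwise_auc(y, scores))
  }
  # label-independent scores concentrate near one half
  set.seed(31)
  y <- rep(c("A", "N"), 500)
  expect_equal(roc_auc(y, runif(1000)), 0.5, tolerance = 0.06)
  expect_error(roc_auc(rep("A", 5), runif(5)), "both classes")
})

test_that("our AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(37)
  y <- sample(c("A", "N"), 80, replace = TRUE)
  y[1:2] <- c("A", "N")
  s <- rnorm(80) + (y == "A")
  ref <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = s,
                                        levels = c("N", "A"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(roc_auc(y, s), ref, tolerance = 1e-10)
})

test_that("AHI follows the 60/T rule, linearly in the apnea count", {
  expect_equal(compute_ahi(c(rep("A", 40), rep("N", 440))), 5.0)
  expect_equal(compute_ahi(rep("A", 123)), 60)
  expect_equal(compute_ahi(rep("N", 480)), 0)
  # linear in count at fixed T
  for (n in c(0, 10, 77, 480)) {
    expect_equal(compute_ahi(n, t_minutes = 480), n * 60 / 480)
  }
  expect_error(compute_ahi(5), "t_minutes")
})

test_that("per-recording diagnosis applies the AHI > 5 rule with Pearson agreement", {
  d <- data.frame(record_id = c("a", "b", "c", "d"),
                  estimated_ahi = c(0, 3, 12, 30),
                  true_ahi = c(0, 3, 12, 30))
  out <- diagnose_recordings(d)
  expect_equal(unname(out$metrics["accuracy"]), 1)
  expect_equal(out$correlation, 1)
  expect_equal(out$table$predicted, c("NORMAL", "NORMAL", "SA", "SA"))
  # correlation is shift-invariant
  d2 <- d
  d2$estimated_ahi <- d$true_ahi + 2
  expect_equal(diagnose_recordings(d2)$correlation, 1)
  # anti-ordered AHIs on three recordings give r = -1
  d3 <- data.frame(record_id = c("x", "y", "z"),
                   estimated_ahi = c(30, 20, 10),
                   true_ahi = c(10, 20, 30))
  expect_equal(diagnose_recordings(d3)$correlation, -1)
  # zero variance flags the correlation undefined
  d4 <- data.frame(record_id = c("x", "y"), estimated_ahi = c(7, 7),
                   true_ahi = c(7, 7))
  expect_warning(out4 <- diagnose_recordings(d4), "undefined")
  expect_true(is.na(out4$correlation))
})

test_that("cross-validation folds partition recordings without leakage", {
  # toy cohort: per-recording labels only; a trivial majority-vote pipeline
  # that records which training recordings it saw
  make_el <- function(i) list(record_id = sprintf("r%02d", i),
                              labels = rep(c("A", "N"),
                                           c(i %% 5, 10 - i %% 5)))
  cohort <- lapply(1:20, make_el)
  seen <- list()
  pipeline <- list(
    fit = function(train_el) {
      ids <- vapply(train_el, function(el) el$record_id, character(1))
      seen[[length(seen) + 1]] <<- ids
      maj <- names(which.max(table(unlist(lapply(train_el,
                                                 function(el) el$labels)))))
      maj
    },
    predict = function(fit, el) rep(fit, length(el$labels)))
  cv <- ten_fold_cv(cohort, pipeline, seed = 5)
  # every recording sits in exactly one test fold
  expect_length(cv$fold_assignment, 20)
  expect_true(all(table(cv$fold_assignment) == 2))
  # leakage audit: a test recording never appears in its fold's training set
  ids <- names(cv$fold_assignment)
  for (k in 1:10) {
    test_ids <- ids[cv$fold_assignment == k]
    expect_length(intersect(test_ids, seen[[k]]), 0)
    expect_setequal(c(test_ids, seen[[k]]), ids)
  }
  # deterministic under the seed
  cv2 <- ten_fold_cv(cohort, pipeline, seed = 5)
  expect_identical(cv$fold_assignment, cv2$fold_assignment)
  expect_error(ten_fold_cv(cohort[1:5], pipeline), "at least 10")
})
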