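#' Confusion counts for binary apnea classification
#'
#' @param truth true labels in `c("A", "N")` (apnea is the positive class).
#' @param pred predicted labels, same coding and length.
#' @return An object of class `confusion_counts`: list with `tp`, `tn`,
#'   `fp`, `fn`.
#' @export
confusion_counts <- function(truth, pred) {
  truth <- as.character(truth)
  pred <- as.character(pred)
  if (length(truth) != length(pred)) {
    stop_validation("truth and pred must have equal length")
  }
  structure(list(tp = sum(truth == APNEA & pred == APNEA),
                 tn = sum(truth == NORMAL & pred == NORMAL),
                 fp = sum(truth == NORMAL & pred == APNEA),
                 fn = sum(truth == APNEA & pred == NORMAL)),
            class = "confusion_counts")
}

#' Specificity, sensitivity and accuracy from confusion counts
#'
#' `specificity = TN/(TN+FP)`, `sensitivity = TP/(TP+FN)`,
#' `accuracy = (TP+TN)/(TP+TN+FP+FN)`. A zero denominator yields `NA` for
#' that metric (with a warning), never an error.
#'
#' @param counts a [confusion_counts()] object, or a list with `tp`, `tn`,
#'   `fp`, `fn`.
#' @return Named numeric vector `specificity`, `sensitivity`, `accuracy`.
#' @export
#' @examples
#' segment_metrics(list(tp = 3, tn = 4, fp = 1, fn = 2))
segment_metrics <- function(counts) {
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator)", what))
      return(NA_real_)
    }
    num / den
  }
  with(counts, c(
    specificity = safe_div(tn, tn + fp, "specificity"),
    sensitivity = safe_div(tp, tp + fn, "sensitivity"),
    accuracy = safe_div(tp + tn, tp + tn + fp + fn, "accuracy")))
}

#' Area under the ROC curve
#'
#' Computed in the Mann-Whitney rank form (equivalent to the trapezoidal
#' area under the threshold-swept ROC with tied scores rank-averaged): the
#' probability that a random apnea window outscores a random normal window,
#' counting ties as one half.
#'
#' @param y labels in `c("A", "N")`; both classes must be present.
#' @param scores numeric apnea scores (higher = more apnea-like).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(y, scores) {
  y <- as.character(y)
  pos <- y == APNEA
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop_validation("both classes must be present for ROC analysis")
  }
  r <- rank(scores)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Apnea-hypopnea index from per-minute labels
#'
#' `AHI = 60 / T * n` where `T` is the number of one-minute segments and
#' `n` the number of apnea segments — apnea events per hour of recording.
#'
#' @param labels per-minute labels in `c("A", "N")` (character vector or
#'   [minute_labels]), or a single apnea count when `t_minutes` is given.
#' @param t_minutes number of one-minute segments (defaults to
#'   `length(labels)`).
#' @return AHI in events/hour.
#' @export
#' @examples
#' compute_ahi(c(rep("A", 40), rep("N", 440)))  # 5
compute_ahi <- function(labels, t_minutes = NULL) {
  if (inherits(labels, "minute_labels")) labels <- labels$labels
  if (is.character(labels)) {
    n <- sum(labels == APNEA)
    if (is.null(t_minutes)) t_minutes <- length(labels)
  } else {
    n <- as.numeric(labels)
    if (is.null(t_minutes)) {
      stop_validation("t_minutes required when passing a count")
    }
  }
  if (is.null(t_minutes) || t_minutes < 1) {
    stop_validation("t_minutes must be >= 1")
  }
  60 / t_minutes * n
}

#' Per-recording SA diagnosis and AHI agreement
#'
#' Applies the clinical rule — a recording with `AHI > 5` is diagnosed as
#' sleep apnea — to both estimated and reference AHI values, then reports
#' the recording-level confusion counts, specificity/sensitivity/accuracy,
#' the AUC of the estimated AHI as a continuous score, and the Pearson
#' correlation between estimated and reference AHI.
#'
#' @param diags data.frame with columns `record_id`, `estimated_ahi`,
#'   `true_ahi`.
#' @param threshold diagnosis threshold (default 5 events/hour).
#' @return List with `table` (per-recording diagnoses), `counts`, `metrics`,
#'   `auc` (NA when only one truth class), `correlation` (NA with a warning
#'   when AHI variance is zero).
#' @export
diagnose_recordings <- function(diags, threshold = 5) {
  req <- c("record_id", "estimated_ahi", "true_ahi")
  if (!all(req %in% names(diags))) {
    stop_validation("diags needs columns record_id, estimated_ahi, true_ahi")
  }
  tab <- data.frame(
    record_id = diags$record_id,
    estimated_ahi = diags$estimated_ahi,
    true_ahi = diags$true_ahi,
    predicted = ifelse(diags$estimated_ahi > threshold, "SA", "NORMAL"),
    truth = ifelse(diags$true_ahi > threshold, "SA", "NORMAL"),
    stringsAsFactors = FALSE)
  truth <- ifelse(tab$truth == "SA", APNEA, NORMAL)
  pred <- ifelse(tab$predicted == "SA", APNEA, NORMAL)
  counts <- confusion_counts(truth, pred)
  metrics <- suppressWarnings(segment_metrics(counts))
  auc <- if (length(unique(truth)) == 2) {
    roc_auc(truth, tab$estimated_ahi)
  } else NA_real_
  correlation <- if (nrow(tab) >= 2 &&
                     sd(tab$true_ahi) > 0 && sd(tab$estimated_ahi) > 0) {
    cor(tab$estimated_ahi, tab$true_ahi)
  } else {
    warning("AHI correlation undefined (fewer than 2 recordings or zero variance)")
    NA_real_
  }
  list(table = tab, counts = counts, metrics = metrics, auc = auc,
       correlation = correlation)
}

#' Recording-level k-fold cross-validation
#'
#' Randomly partitions recordings into folds (default 10); each fold is
#' tested once with the model trained on the remaining folds. Folding is at
#' the recording level, so no minute of a test recording ever reaches
#' training — the assignment is returned for leakage audits.
#'
#' @param cohort list of per-recording elements; each element must carry the
#'   data the pipeline consumes, and a `record_id`.
#' @param pipeline list with functions `fit(train_elements)` and
#'   `predict(model, element)`; `predict` must return per-minute labels in
#'   `c("A", "N")` for that recording.
#' @param true_labels function mapping an element to its per-minute truth
#'   labels (default `function(el) el$labels`).
#' @param n_folds number of folds (default 10).
#' @param seed RNG seed fixing the fold assignment.
#' @return List with `fold_assignment` (named by record_id), `fold_accuracy`,
#'   `mean_accuracy`, `sd_accuracy`.
#' @export
ten_fold_cv <- function(cohort, pipeline,
                        true_labels = function(el) el$labels,
                        n_folds = 10L, seed = 1L) {
  n <- length(cohort)
  if (n < n_folds) {
    stop_validation(sprintf("need at least %d recordings for %d-fold CV",
                            n_folds, n_folds))
  }
  ids <- vapply(cohort, function(el) el$record_id, character(1))
  folds <- with_seed(seed, {
    perm <- sample.int(n)
    f <- integer(n)
    f[perm] <- rep_len(seq_len(n_folds), n)
    f
  })
  names(folds) <- ids
  acc <- numeric(n_folds)
  for (k in seq_len(n_folds)) {
    test_el <- cohort[folds == k]
    train_el <- cohort[folds != k]
    fit <- pipeline$fit(train_el)
    correct <- 0L
    total <- 0L
    for (el in test_el) {
      pred <- pipeline$predict(fit, el)
      truth <- true_labels(el)
      correct <- correct + sum(pred == truth)
      total <- total + length(truth)
    }
    acc[k] <- correct / total
  }
  list(fold_assignment = folds,
       fold_accuracy = acc,
       mean_accuracy = mean(acc),
       sd_accuracy = sd(acc))
}
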