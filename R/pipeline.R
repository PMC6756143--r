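#' Preprocess one simulated (or real) recording into pipeline inputs
#'
#' Runs the full preprocessing chain and feature extraction once, yielding
#' the per-recording element consumed by the cross-validation harness and
#' the holdout evaluator: context windows for the CNN, the 18-column HRV
#' feature table for the baselines, the truth labels and the reference AHI.
#'
#' @param sim a `sim_recording`, or a list with `recording`
#'   ([ecg_recording]) and `labels` ([minute_labels]).
#' @param ... passed to [build_dataset()].
#' @return List with `record_id`, `windows`, `features` (data.frame),
#'   `labels` (character vector), `true_ahi`.
#' @export
prepare_recording <- function(sim, ...) {
  rec <- sim$recording
  labels <- sim$labels
  windows <- build_dataset(rec, labels, ...)
  feats <- extract_feature_matrix(windows)
  list(record_id = rec$record_id,
       windows = windows,
       features = feats,
       labels = labels$labels,
       true_ahi = compute_ahi(labels$labels))
}

#' Preprocess a whole cohort
#'
#' @param cohort a `sim_cohort` (list of `sim_recording`s).
#' @param ... passed to [prepare_recording()].
#' @return List of prepared elements.
#' @export
prepare_cohort <- function(cohort, ...) {
  lapply(cohort, prepare_recording, ...)
}

#' End-to-end CNN pipeline for the cross-validation harness
#'
#' @param spec architecture, default [modified_lenet5_spec()].
#' @param cfg a [train_config()].
#' @return List with `fit(train_elements)` and `predict(model, element)`
#'   closures matching the [ten_fold_cv()] contract.
#' @export
cnn_pipeline <- function(spec = modified_lenet5_spec(),
                         cfg = train_config()) {
  list(
    fit = function(train_elements) {
      windows <- do.call(c, lapply(train_elements,
                                   function(el) unclass(el$windows)))
      model <- build_model(spec, seed = cfg$seed)
      train_cnn(model, windows, cfg)
    },
    predict = function(model, element) {
      predict_proba(model, element$windows)$label
    },
    score = function(model, element) {
      predict_proba(model, element$windows)$prob_apnea
    })
}

#' End-to-end feature-baseline pipeline for the cross-validation harness
#'
#' Fits the min-max scaling on the pooled training features, then the
#' requested baseline classifier.
#'
#' @param cfg a [baseline_config()].
#' @return List with `fit` / `predict` / `score` closures as in
#'   [cnn_pipeline()].
#' @export
baseline_pipeline <- function(cfg = baseline_config("svm")) {
  feat_mat <- function(el) as.matrix(el$features[, FEATURE_NAMES])
  list(
    fit = function(train_elements) {
      x <- do.call(rbind, lapply(train_elements, feat_mat))
      y <- do.call(c, lapply(train_elements, function(el) el$labels))
      sc <- minmax_fit_transform(x)
      list(model = fit_baseline(cfg, sc$train, y), scaling = sc$scaling)
    },
    predict = function(fit, element) {
      x <- feat_mat(element)
      xn <- minmax_apply(fit$scaling, x)
      predict_baseline(fit$model, xn)$label
    },
    score = function(fit, element) {
      x <- feat_mat(element)
      xn <- minmax_apply(fit$scaling, x)
      predict_baseline(fit$model, xn)$score
    })
}

# Apply a fitted min-max scaling to new rows.
minmax_apply <- function(scaling, x) {
  rng <- scaling$max - scaling$min
  out <- sweep(as.matrix(x), 2, scaling$min, "-")
  out <- sweep(out, 2, ifelse(rng > 0, rng, 1), "/")
  out[, rng == 0] <- 0
  out
}

#' Train on part of a cohort, evaluate per-segment and per-recording
#'
#' The holdout analogue of the benchmark's released/withheld design: fit the
#' pipeline on the training recordings, then report per-segment confusion
#' metrics and AUC over all test minutes pooled, and the per-recording AHI
#' diagnosis (AHI from predicted minute labels vs AHI from expert labels).
#'
#' @param prepared list from [prepare_cohort()].
#' @param pipeline a [cnn_pipeline()] or [baseline_pipeline()].
#' @param train_idx indices of training recordings; the rest are tested.
#' @return List with `segment` (counts, metrics, auc), `recording`
#'   (output of [diagnose_recordings()]), `majority_rate` (largest-class
#'   fraction of the test minutes), and `fit`.
#' @export
evaluate_holdout <- function(prepared, pipeline, train_idx) {
  test_idx <- setdiff(seq_along(prepared), train_idx)
  if (length(test_idx) == 0) stop_validation("no test recordings left")
  fit <- pipeline$fit(prepared[train_idx])
  truth_all <- character(0)
  pred_all <- character(0)
  score_all <- numeric(0)
  diags <- data.frame(record_id = character(0), estimated_ahi = numeric(0),
                      true_ahi = numeric(0))
  for (el in prepared[test_idx]) {
    pred <- pipeline$predict(fit, el)
    score <- pipeline$score(fit, el)
    truth_all <- c(truth_all, el$labels)
    pred_all <- c(pred_all, pred)
    score_all <- c(score_all, score)
    diags <- rbind(diags, data.frame(record_id = el$record_id,
                                     estimated_ahi = compute_ahi(pred),
                                     true_ahi = el$true_ahi))
  }
  counts <- confusion_counts(truth_all, pred_all)
  metrics <- suppressWarnings(segment_metrics(counts))
  auc <- if (length(unique(truth_all)) == 2) {
    roc_auc(truth_all, score_all)
  } else NA_real_
  majority <- max(table(truth_all)) / length(truth_all)
  list(segment = list(counts = counts, metrics = metrics, auc = auc),
       recording = suppressWarnings(diagnose_recordings(diags)),
       majority_rate = as.numeric(majority),
       fit = fit)
}
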