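#' Configuration for a feature-engineering baseline classifier
#'
#' The four comparison methods operate on the 18 min-max-normalized HRV
#' features: an RBF-kernel SVM, L2 (ridge) logistic regression, k-nearest
#' neighbours and a single-hidden-layer MLP. Hyperparameters follow common
#' defaults and are all exposed here.
#'
#' @param name one of `"svm"`, `"lr"`, `"knn"`, `"mlp"`.
#' @param cost SVM soft-margin cost (default 1).
#' @param k neighbours for KNN (default 5).
#' @param hidden hidden-layer size for the MLP (default 32).
#' @param lambda ridge penalty for LR (default 0.01).
#' @param seed RNG seed (MLP weight init; KNN tie-breaks).
#' @return A `baseline_config` list.
#' @export
baseline_config <- function(name = c("svm", "lr", "knn", "mlp"),
                            cost = 1, k = 5L, hidden = 32L,
                            lambda = 0.01, seed = 1L) {
  name <- match.arg(name)
  stopifnot(cost > 0, k >= 1, hidden >= 1, lambda >= 0)
  structure(list(name = name, cost = cost, k = as.integer(k),
                 hidden = as.integer(hidden), lambda = lambda,
                 seed = as.integer(seed)),
            class = "baseline_config")
}

#' Fit a baseline classifier on normalized features
#'
#' All four baselines share this contract: fit on an `n x 18` matrix of
#' min-max-normalized features and a binary label vector, and expose a
#' continuous apnea score through [predict_baseline()] suitable for ROC
#' analysis.
#'
#' @param cfg a [baseline_config()].
#' @param x numeric feature matrix (rows = windows).
#' @param y labels in `c("A", "N")`, both classes present.
#' @return An object of class `apnea_baseline`.
#' @export
fit_baseline <- function(cfg, x, y) {
  x <- as.matrix(x)
  y <- as.character(y)
  if (length(unique(y)) < 2) {
    stop_validation("training labels must contain both classes")
  }
  yf <- factor(y, levels = CLASS_LEVELS)
  fit <- with_seed(cfg$seed, switch(
    cfg$name,
    svm = e1071::svm(x, yf, kernel = "radial", cost = cfg$cost,
                     probability = TRUE),
    lr = glmnet::glmnet(x, yf, family = "binomial", alpha = 0,
                        lambda = cfg$lambda),
    knn = list(x = x, y = yf),  # KNN is lazy: keep the training data
    mlp = nnet::nnet(x, stats::model.matrix(~ yf - 1),
                     size = cfg$hidden, decay = 1e-4, maxit = 200,
                     softmax = TRUE, trace = FALSE, MaxNWts = 5000)))
  structure(list(cfg = cfg, fit = fit, n_features = ncol(x)),
            class = "apnea_baseline")
}

#' Predict apnea labels and scores with a fitted baseline
#'
#' @param model an `apnea_baseline`.
#' @param x feature matrix with the same number of columns as at fit time.
#' @return List with `label` (in `c("A", "N")`, 0.5 score threshold) and
#'   `score` (probability-like apnea score, monotone for ROC use).
#' @export
predict_baseline <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != model$n_features) {
    stop_validation(sprintf("expected %d feature columns, got %d",
                            model$n_features, ncol(x)))
  }
  cfg <- model$cfg
  score <- switch(
    cfg$name,
    svm = {
      pr <- attr(predict(model$fit, x, probability = TRUE), "probabilities")
      as.numeric(pr[, APNEA])
    },
    lr = {
      # glmnet codes the second factor level as the modelled class
      as.numeric(predict(model$fit, x, type = "response", s = cfg$lambda))
    },
    knn = with_seed(cfg$seed, {
      pred <- class::knn(model$fit$x, x, model$fit$y, k = cfg$k,
                         prob = TRUE)
      p_win <- attr(pred, "prob")
      ifelse(pred == APNEA, p_win, 1 - p_win)
    }),
    mlp = {
      pr <- predict(model$fit, x)
      as.numeric(pr[, match(paste0("yf", APNEA), colnames(pr))])
    })
  list(label = ifelse(score >= 0.5, APNEA, NORMAL), score = score)
}
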