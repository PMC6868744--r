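# Confusion-matrix metrics, rank-based ROC AUC, and the stratified
# cross-validation harness.

#' Cross-validation specification
#'
#' @param n_folds Number of stratified folds (default 10).
#' @param seed Seed controlling the fold assignment (and, in model
#'   training, all downstream randomness).
#' @return List of class `cv_spec`.
#' @export
cv_spec <- function(n_folds = 10, seed = 1) {
  stopifnot(n_folds >= 2)
  structure(list(n_folds = as.integer(n_folds), stratified = TRUE,
                 seed = as.integer(seed)),
            class = "cv_spec")
}

#' Stratified fold assignment
#'
#' Samples are shuffled within each class (seeded) and dealt
#' round-robin, so every fold's class ratio is within one sample of the
#' global ratio and every fold holds at least one sample of each class.
#'
#' @param labels Class labels (`positive`/`negative`, 0/1 or logical).
#' @param cv A [cv_spec()].
#' @return Integer vector of fold ids in `1..n_folds`.
#' @export
make_cv_folds <- function(labels, cv = cv_spec()) {
  y <- as_binary_labels(labels)
  counts <- table(y)
  if (any(counts < cv$n_folds))
    stop("class '", names(counts)[which.min(counts)], "' has only ",
         min(counts), " samples; use n_folds <= ", min(counts))
  folds <- integer(length(y))
  with_local_seed(cv$seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(cv$n_folds), length(idx))
    }
  })
  folds
}

#' Confusion-matrix metrics
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy
#' (TP+TN)/N and the Matthews correlation coefficient
#' (TP*TN - FP*FN) / sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN)).
#' S-sulphenylated sites are the positive class. When the MCC
#' denominator is zero the MCC is reported as 0 (logged convention).
#'
#' @param labels True labels.
#' @param predicted Predicted labels.
#' @return List of class `sulfen_metrics`: tp, tn, fp, fn,
#'   sensitivity, specificity, accuracy, mcc.
#' @examples
#' confusion_metrics(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusion_metrics <- function(labels, predicted) {
  if (length(labels) == 0) stop("empty input")
  y <- as_binary_labels(labels)
  p <- as_binary_labels(predicted)
  stopifnot(length(y) == length(p))
  tp <- sum(y == "positive" & p == "positive")
  tn <- sum(y == "negative" & p == "negative")
  fp <- sum(y == "negative" & p == "positive")
  fn <- sum(y == "positive" & p == "negative")
  denom <- sqrt(prod(c(tp + fn, tn + fp, tp + fp, tn + fn)))
  mcc <- if (denom == 0) {
    message("MCC denominator is 0; reporting MCC = 0")
    0
  } else (tp * tn - fp * fn) / denom
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 accuracy = (tp + tn) / length(y),
                 mcc = mcc),
            class = "sulfen_metrics")
}

#' @export
print.sulfen_metrics <- function(x, ...) {
  cat(sprintf("TP %d  TN %d  FP %d  FN %d\n", x$tp, x$tn, x$fp, x$fn))
  cat(sprintf("sensitivity %.3f  specificity %.3f  accuracy %.3f  MCC %.3f",
              x$sensitivity, x$specificity, x$accuracy, x$mcc))
  if (!is.null(x$auc)) cat(sprintf("  AUC %.3f", x$auc))
  cat("\n")
  invisible(x)
}

#' Rank-based ROC AUC
#'
#' The Mann-Whitney formulation with tie correction: the probability
#' that a random positive scores higher than a random negative, ties
#' counting one half. Equals the trapezoidal area under the ROC curve.
#'
#' @param labels True labels (both classes must be present).
#' @param scores Numeric scores, larger for more positive.
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)) # 0.75
#' @export
roc_auc <- function(labels, scores) {
  y <- as_binary_labels(labels)
  stopifnot(length(y) == length(scores))
  npos <- sum(y == "positive"); nneg <- sum(y == "negative")
  if (npos == 0 || nneg == 0)
    stop("both classes must be present to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == "positive"]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Cross-validate a scoring pipeline
#'
#' Runs seed-fixed stratified cross-validation: `fit_fun(x, y)` is
#' trained on each training split and must return a function mapping a
#' feature matrix to positive-class scores. Pooled metrics are computed
#' on the concatenated out-of-fold scores (the headline numbers);
#' per-fold metrics are also returned.
#'
#' @param x Feature matrix (samples x features).
#' @param labels Class labels.
#' @param fit_fun Function `(x_train, y_train) -> function(x_new)`.
#' @param cv A [cv_spec()].
#' @param threshold Probability cutoff for label metrics (default 0.5).
#' @return List with `pooled` (a `sulfen_metrics` including `auc`),
#'   `per_fold` (data.frame of fold metrics), `oof` (out-of-fold
#'   scores) and `folds`.
#' @export
cross_validate <- function(x, labels, fit_fun, cv = cv_spec(),
                           threshold = 0.5) {
  y <- as_binary_labels(labels)
  folds <- make_cv_folds(y, cv)
  oof <- numeric(length(y))
  per_fold <- vector("list", cv$n_folds)
  for (f in seq_len(cv$n_folds)) {
    tr <- folds != f
    scorer <- fit_fun(x[tr, , drop = FALSE], y[tr])
    s <- scorer(x[!tr, , drop = FALSE])
    oof[!tr] <- s
    m <- confusion_metrics(y[!tr],
                           ifelse(s >= threshold, "positive", "negative"))
    m$auc <- roc_auc(y[!tr], s)
    per_fold[[f]] <- data.frame(fold = f, auc = m$auc,
                                sensitivity = m$sensitivity,
                                specificity = m$specificity,
                                accuracy = m$accuracy, mcc = m$mcc)
  }
  pooled <- confusion_metrics(y, ifelse(oof >= threshold,
                                        "positive", "negative"))
  pooled$auc <- roc_auc(y, oof)
  list(pooled = pooled, per_fold = do.call(rbind, per_fold),
       oof = oof, folds = folds)
}
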