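# High-level training pipeline: encode -> rank -> select -> stack.

#' Train an S-sulphenylation predictor end to end
#'
#' Assembles the feature matrix, ranks features by mRMR, runs forward
#' incremental selection, and trains the two-stage stacked ensemble.
#' All randomness (fold assignment, forests, network initialization)
#' flows from the single `seed`.
#'
#' @param dataset A labelled [motif_dataset()] (labels `positive` /
#'   `negative`).
#' @param store An [annotation_store()] covering the dataset's
#'   proteins; required unless `blocks` is restricted to sequence
#'   clusters.
#' @param blocks Feature clusters to use (default all nine).
#' @param encoder_cfg An [encoder_config()].
#' @param stack_cfg A [stack_config()].
#' @param select Run mRMR + forward selection and add the selected set
#'   as a tenth feature set (default `TRUE`).
#' @param n_rank Number of features to mRMR-rank before forward
#'   selection (default 100).
#' @param patience Forward-selection stopping patience (default 20).
#' @param n_folds Stratified CV folds for stage-1 stacking (default
#'   10).
#' @param inner_folds CV folds inside the selection loop (default 5).
#' @param units,decay Stage-2 network hyperparameters (defaults 1,
#'   0.1).
#' @param seed Master seed.
#' @return A `stacked_model` (with the `selection_result` attached as
#'   `$selection` when selection ran).
#' @export
sulfen_train <- function(dataset, store = NULL, blocks = CLUSTER_NAMES,
                         encoder_cfg = encoder_config(),
                         stack_cfg = stack_config(), select = TRUE,
                         n_rank = 100, patience = 20, n_folds = 10,
                         inner_folds = 5, units = 1, decay = 0.1,
                         seed = 1) {
  stopifnot(inherits(dataset, "motif_dataset"))
  if (!all(dataset$label %in% c("positive", "negative")))
    stop("training data must be labelled positive/negative")
  labels <- dataset$label
  fm <- assemble_feature_matrix(dataset, store, encoder_cfg, blocks)
  selection <- NULL
  if (select) {
    ranking <- mrmr_rank(fm, labels, n = min(n_rank, ncol(fm$values)))
    selection <- forward_incremental_select(
      ranking, fm, labels, cv = cv_spec(inner_folds, seed = seed),
      patience = patience)
    if (length(selection$selected) == 0) {
      warning("forward selection kept no feature; ",
              "training without the SELECTED set")
      selection_for_stack <- NULL
    } else selection_for_stack <- selection
  } else selection_for_stack <- NULL
  model <- train_stacked(fm, labels, selection_for_stack,
                         cv = cv_spec(n_folds, seed = seed),
                         config = stack_cfg, units = units,
                         decay = decay)
  model$selection <- selection
  model
}

#' Score a set of predictions
#'
#' Confusion-matrix metrics at a probability threshold plus the
#' rank-based AUC.
#'
#' @param labels True labels.
#' @param scores Predicted positive-class probabilities.
#' @param threshold Label cutoff (default 0.5).
#' @return A `sulfen_metrics` object including `auc`.
#' @export
metrics_from_scores <- function(labels, scores, threshold = 0.5) {
  m <- confusion_metrics(labels, ifelse(scores >= threshold,
                                        "positive", "negative"))
  m$auc <- roc_auc(labels, scores)
  m
}
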