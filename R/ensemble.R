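# Two-stage stacked ensemble: per-feature-set random forests and SVMs
# (stage 1) whose out-of-fold probabilities feed a small feed-forward
# neural network (stage 2). Out-of-fold stacking is used deliberately:
# meta-training on in-sample base-model scores leaks the training
# labels and is rejected by the no-leakage tests.

MODEL_VERSION <- "sulfenR-model-1"

#' Stage-1 model configuration
#'
#' @param kernels SVM kernels tried per feature set; the kernel with
#'   the best out-of-fold AUC is kept.
#' @param min_trees Floor on the number of RF trees. The number of
#'   trees is the rounded square root of the feature count, which for
#'   small blocks (e.g. 20 columns) gives a statistically meaningless
#'   forest, so it is floored at 100 by default.
#' @param literal_trees If `TRUE`, use the un-floored square-root tree
#'   count.
#' @param cost SVM cost parameter.
#' @return List of class `stack_config`.
#' @export
stack_config <- function(kernels = c("linear", "polynomial", "radial"),
                         min_trees = 100, literal_trees = FALSE,
                         cost = 1) {
  kernels <- match.arg(kernels, c("linear", "polynomial", "radial"),
                       several.ok = TRUE)
  structure(list(kernels = kernels, min_trees = min_trees,
                 literal_trees = literal_trees, cost = cost),
            class = "stack_config")
}

# --- SVM wrapper: standardization + Platt-calibrated probabilities ----

svm_fit <- function(x, y, kernel, cost = 1) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[sdv == 0] <- 1
  z <- sweep(sweep(x, 2, mu), 2, sdv, `/`)
  m <- e1071::svm(x = z, y = y, kernel = kernel, cost = cost,
                  scale = FALSE)
  dv <- as.numeric(attr(predict(m, z, decision.values = TRUE),
                        "decision.values"))
  y01 <- as.numeric(y == "positive")
  # Platt scaling: logistic fit of the labels on the decision values
  platt <- suppressWarnings(glm(y01 ~ dv, family = binomial()))
  co <- stats::coef(platt)
  co[is.na(co)] <- 0
  list(svm = m, center = mu, scale = sdv, platt = co, kernel = kernel)
}

svm_decision <- function(model, xnew) {
  z <- sweep(sweep(xnew, 2, model$center), 2, model$scale, `/`)
  as.numeric(attr(predict(model$svm, z, decision.values = TRUE),
                  "decision.values"))
}

svm_score <- function(model, xnew) {
  dv <- svm_decision(model, xnew)
  plogis(model$platt[1] + model$platt[2] * dv)
}

rf_fit <- function(x, y, num.trees, seed) {
  counts <- table(y)
  wts <- as.numeric(length(y) / (2 * counts[levels(y)]))
  ranger::ranger(y = y, x = x, num.trees = num.trees, probability = TRUE,
                 class.weights = wts, seed = seed, num.threads = 1)
}

rf_score <- function(model, xnew) {
  predict(model, xnew, num.threads = 1)$predictions[, "positive"]
}

#' Train the stage-1 base learners
#'
#' For every feature set, fits a balanced-class-weight random forest
#' (tree count = rounded square root of the feature count, floored per
#' `config`) and an SVM whose kernel is chosen by out-of-fold
#' cross-validated AUC, with Platt-calibrated probability outputs.
#' Returns the out-of-fold positive-class probabilities of every
#' sample under every model — the stacking inputs for the stage-2
#' network — plus models refit on the full training data for
#' prediction time.
#'
#' @param x Feature matrix or `feature_matrix`.
#' @param labels Class labels.
#' @param sets Named list: feature-set name -> character vector of
#'   column names (e.g. the nine encoder blocks plus the selected set).
#' @param cv A [cv_spec()].
#' @param config A [stack_config()].
#' @return List with `models` (per set: `rf`, `svm`), `oof` (matrix
#'   n x 2 * length(sets), columns `RF.<set>`, `SVM.<set>`), `aucs`
#'   (per-set out-of-fold AUC and chosen kernel) and `folds`.
#' @export
train_base_models <- function(x, labels, sets, cv = cv_spec(),
                              config = stack_config()) {
  if (inherits(x, "feature_matrix")) x <- x$values
  y <- as_binary_labels(labels)
  stopifnot(is.list(sets), length(sets) > 0, !is.null(names(sets)))
  empty <- names(sets)[lengths(sets) == 0]
  if (length(empty) > 0)
    stop("feature set(s) with zero columns: ", paste(empty, collapse = ", "))
  missing_feats <- setdiff(unique(unlist(sets)), colnames(x))
  if (length(missing_feats) > 0)
    stop("feature(s) absent from the matrix: ",
         paste(head(missing_feats, 3), collapse = ", "))
  folds <- make_cv_folds(y, cv)
  n <- length(y)
  oof <- matrix(NA_real_, n, 2 * length(sets))
  colnames(oof) <- as.vector(vapply(names(sets), function(s)
    paste0(c("RF.", "SVM."), s), character(2)))
  models <- vector("list", length(sets))
  names(models) <- names(sets)
  aucs <- vector("list", length(sets))
  for (si in seq_along(sets)) {
    sname <- names(sets)[si]
    xs <- x[, sets[[si]], drop = FALSE]
    p <- ncol(xs)
    nt <- round(sqrt(p))
    if (!config$literal_trees) nt <- max(config$min_trees, nt)
    seed0 <- cv$seed + 101L * si
    # RF out-of-fold probabilities
    rf_oof <- numeric(n)
    for (f in seq_len(cv$n_folds)) {
      tr <- folds != f
      m <- rf_fit(xs[tr, , drop = FALSE], y[tr], nt, seed0 + f)
      rf_oof[!tr] <- rf_score(m, xs[!tr, , drop = FALSE])
    }
    # SVM: out-of-fold per kernel, keep the best kernel
    svm_oofs <- lapply(config$kernels, function(kern) {
      s <- numeric(n)
      for (f in seq_len(cv$n_folds)) {
        tr <- folds != f
        m <- svm_fit(xs[tr, , drop = FALSE], y[tr], kern, config$cost)
        s[!tr] <- svm_score(m, xs[!tr, , drop = FALSE])
      }
      s
    })
    svm_aucs <- vapply(svm_oofs, function(s) roc_auc(y, s), numeric(1))
    best <- which.max(svm_aucs)
    oof[, paste0("RF.", sname)] <- rf_oof
    oof[, paste0("SVM.", sname)] <- svm_oofs[[best]]
    models[[sname]] <- list(
      rf = rf_fit(xs, y, nt, seed0),
      svm = svm_fit(xs, y, config$kernels[best], config$cost),
      num.trees = nt)
    aucs[[si]] <- data.frame(set = sname,
                             rf_auc = roc_auc(y, rf_oof),
                             svm_auc = svm_aucs[best],
                             svm_kernel = config$kernels[best],
                             stringsAsFactors = FALSE)
  }
  list(models = models, oof = oof, aucs = do.call(rbind, aucs),
       folds = folds)
}

#' Train the stage-2 neural network
#'
#' A single-hidden-layer feed-forward network with logistic
#' activations, bias units in hidden and output layers, and L2 weight
#' decay, trained on the stage-1 out-of-fold probability matrix (one
#' input node per base model, 20 by default). Defaults: 1 hidden unit,
#' decay 0.1.
#'
#' @param oof Matrix of stage-1 out-of-fold probabilities
#'   (samples x base models).
#' @param labels Class labels.
#' @param units Hidden units (default 1).
#' @param decay L2 weight decay (default 0.1).
#' @param seed Seed for the weight initialization.
#' @param maxit Optimizer iteration cap (BFGS inside [nnet::nnet()]).
#' @return List of class `meta_net` with the fitted network and its
#'   input manifest.
#' @export
train_meta_network <- function(oof, labels, units = 1, decay = 0.1,
                               seed = 1, maxit = 1000) {
  oof <- as.matrix(oof)
  if (!all(is.finite(oof))) stop("non-finite stacking inputs")
  y01 <- as.numeric(as_binary_labels(labels) == "positive")
  net <- with_local_seed(seed,
    nnet::nnet(x = oof, y = y01, size = units, decay = decay,
               entropy = TRUE, maxit = maxit, trace = FALSE))
  structure(list(net = net, inputs = colnames(oof), units = units,
                 decay = decay, seed = seed),
            class = "meta_net")
}

predict_meta <- function(meta, scores) {
  scores <- as.matrix(scores)
  if (!is.null(meta$inputs)) {
    if (!all(meta$inputs %in% colnames(scores)))
      stop("stacking inputs do not match the meta-network manifest")
    scores <- scores[, meta$inputs, drop = FALSE]
  }
  as.numeric(predict(meta$net, scores))
}

#' Grid search over the meta-network hyperparameters
#'
#' Cross-validated AUC of the stage-2 network over a (hidden units x
#' weight decay) grid, default `{1, 3, 5} x {0, 4e-4, 0.1}`.
#'
#' @inheritParams train_meta_network
#' @param units Hidden-unit counts to try.
#' @param decays Weight-decay values to try.
#' @param cv A [cv_spec()].
#' @return Numeric matrix of pooled CV AUC, rows = units, columns =
#'   decay.
#' @export
meta_grid_search <- function(oof, labels, units = c(1, 3, 5),
                             decays = c(0, 4e-4, 0.1),
                             cv = cv_spec()) {
  y <- as_binary_labels(labels)
  out <- matrix(NA_real_, length(units), length(decays),
                dimnames = list(paste0("units", units),
                                paste0("decay", decays)))
  for (i in seq_along(units)) {
    for (j in seq_along(decays)) {
      res <- cross_validate(as.matrix(oof), y, function(xtr, ytr) {
        meta <- train_meta_network(xtr, ytr, units = units[i],
                                   decay = decays[j], seed = cv$seed)
        function(xte) predict_meta(meta, xte)
      }, cv = cv)
      out[i, j] <- res$pooled$auc
    }
  }
  out
}

#' Train the full two-stage stacked model
#'
#' Stage 1 trains one RF and one SVM per feature set (the nine encoder
#' blocks of `fm`, plus the selected feature subset when a
#' `selection_result` is supplied, giving 20 base models). Stage 2
#' trains the meta network on the out-of-fold stage-1 probabilities.
#' The returned model carries the feature manifest, encoder
#' configuration and normalization constants needed to encode and
#' score new motifs.
#'
#' @param fm A `feature_matrix` from [assemble_feature_matrix()].
#' @param labels Class labels aligned with `fm`.
#' @param selection Optional `selection_result` from
#'   [forward_incremental_select()].
#' @param cv A [cv_spec()] (default 10-fold stratified).
#' @param config A [stack_config()].
#' @param units,decay Stage-2 hyperparameters (defaults 1 and 0.1).
#' @param threshold Probability cutoff for predicted labels.
#' @return List of class `stacked_model`.
#' @export
train_stacked <- function(fm, labels, selection = NULL, cv = cv_spec(),
                          config = stack_config(), units = 1,
                          decay = 0.1, threshold = 0.5) {
  stopifnot(inherits(fm, "feature_matrix"))
  sets <- fm$blocks
  if (!is.null(selection)) {
    stopifnot(inherits(selection, "selection_result"))
    if (length(selection$selected) == 0)
      stop("selection_result has an empty selected set")
    sets$SELECTED <- selection$selected
  }
  base <- train_base_models(fm, labels, sets, cv, config)
  meta <- train_meta_network(base$oof, labels, units = units,
                             decay = decay, seed = cv$seed)
  structure(list(base_models = base$models, sets = sets, meta = meta,
                 base_aucs = base$aucs, oof = base$oof,
                 encoder_config = fm$config, norm = fm$norm,
                 cv = cv, config = config, threshold = threshold,
                 version = MODEL_VERSION),
            class = "stacked_model")
}

#' @export
print.stacked_model <- function(x, ...) {
  cat("stacked_model:", length(x$base_models), "feature sets,",
      2 * length(x$base_models), "base models + meta network (",
      x$meta$units, "hidden unit(s), decay", x$meta$decay, ")\n")
  print(x$base_aucs, row.names = FALSE)
  invisible(x)
}

# Stage-1 + stage-2 scores for an encoded feature matrix.
predict_stacked_scores <- function(model, values) {
  if (inherits(values, "feature_matrix")) values <- values$values
  needed <- unique(unlist(model$sets))
  missing_feats <- setdiff(needed, colnames(values))
  if (length(missing_feats) > 0)
    stop("feature matrix does not match the model manifest; missing: ",
         paste(head(missing_feats, 3), collapse = ", "),
         if (length(missing_feats) > 3) " ...")
  base_scores <- matrix(NA_real_, nrow(values), 2 * length(model$sets))
  colnames(base_scores) <- as.vector(vapply(names(model$sets), function(s)
    paste0(c("RF.", "SVM."), s), character(2)))
  for (sname in names(model$sets)) {
    xs <- values[, model$sets[[sname]], drop = FALSE]
    m <- model$base_models[[sname]]
    base_scores[, paste0("RF.", sname)] <- rf_score(m$rf, xs)
    base_scores[, paste0("SVM.", sname)] <- svm_score(m$svm, xs)
  }
  predict_meta(model$meta, base_scores)
}

#' Predict S-sulphenylation for motifs
#'
#' Encodes the motifs with the training-time manifest and
#' normalization constants, scores them through all base models and
#' the meta network. Deterministic given model and inputs.
#'
#' @param model A `stacked_model`.
#' @param dataset A [motif_dataset()] (or a `feature_matrix` already
#'   encoded with the model's configuration).
#' @param store An [annotation_store()] covering the dataset's
#'   proteins (required when the model uses structural blocks).
#' @return `data.frame` with `protein_id`, `position`, `sequence`,
#'   `probability` and `label` (thresholded at the model's cutoff).
#' @export
predict_stacked <- function(model, dataset, store = NULL) {
  stopifnot(inherits(model, "stacked_model"))
  if (inherits(dataset, "feature_matrix")) {
    prob <- predict_stacked_scores(model, dataset)
    return(data.frame(sample_id = rownames(dataset$values),
                      probability = prob,
                      label = ifelse(prob >= model$threshold,
                                     "positive", "negative"),
                      stringsAsFactors = FALSE))
  }
  stopifnot(inherits(dataset, "motif_dataset"))
  clusters <- intersect(names(model$sets), CLUSTER_NAMES)
  fm <- assemble_feature_matrix(dataset, store,
                                config = model$encoder_config,
                                blocks = clusters, norm = model$norm)
  prob <- predict_stacked_scores(model, fm)
  data.frame(protein_id = dataset$protein_id,
             position = dataset$position,
             sequence = dataset$sequence,
             probability = prob,
             label = ifelse(prob >= model$threshold,
                            "positive", "negative"),
             stringsAsFactors = FALSE)
}

#' Save / load a stacked model
#'
#' The archive bundles base models, meta-network weights,
#' normalization constants, the feature manifest and the
#' configuration; a version string guards against loading archives
#' from incompatible package versions.
#'
#' @param model A `stacked_model`.
#' @param path File path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "stacked_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("not a readable model file: ",
                                           path, " (", conditionMessage(e),
                                           ")", call. = FALSE))
  if (!inherits(obj, "stacked_model"))
    stop("file ", path, " does not contain a stacked model")
  if (!identical(obj$version, MODEL_VERSION))
    stop("model version mismatch: file has '", obj$version,
         "', this package expects '", MODEL_VERSION, "'")
  obj
}
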