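# Feature selection: supervised MDL discretization, mRMR ranking,
# forward incremental selection, and raw out-of-bag permutation
# importance for random forests.

entropy_bits <- function(counts) {
  # counts: matrix (splits x classes) or vector; plug-in entropy, base 2
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  n <- rowSums(counts)
  p <- counts / ifelse(n == 0, 1, n)
  lp <- ifelse(p > 0, log2(p), 0)
  -rowSums(p * lp)
}

#' Supervised MDL discretization (Fayyad-Irani)
#'
#' Recursive entropy-based binning of a continuous feature: at each
#' step the cut minimizing class entropy is accepted only if its
#' information gain exceeds the minimum-description-length cost of
#' encoding the extra partition. Features with no accepted cut collapse
#' to a single bin; constant input yields a single bin without error.
#'
#' @param values Numeric vector.
#' @param labels Class labels (at least 2 classes present for any cut
#'   to be considered).
#' @return List with `codes` (integer bin per observation, 1-based) and
#'   `cutpoints` (increasing numeric vector, possibly empty).
#' @export
mdl_discretize <- function(values, labels) {
  stopifnot(length(values) == length(labels))
  y <- as.integer(factor(labels))
  k_all <- max(y)
  uv <- sort(unique(values))
  nu <- length(uv)
  if (nu < 2) return(list(codes = rep(1L, length(values)),
                          cutpoints = numeric(0)))
  code <- findInterval(values, uv)
  counts <- matrix(tabulate((code - 1L) * k_all + y, nu * k_all),
                   nrow = nu, byrow = TRUE)
  cum <- apply(counts, 2, cumsum)
  if (nu == 2) cum <- matrix(cum, nrow = nu)
  cuts <- numeric(0)
  recurse <- function(lo, hi) {
    if (hi <= lo) return(invisible(NULL))
    tot <- cum[hi, ] - (if (lo > 1) cum[lo - 1, ] else 0)
    N <- sum(tot)
    if (N < 2) return(invisible(NULL))
    s <- lo:(hi - 1)
    left <- cum[s, , drop = FALSE] -
      matrix(if (lo > 1) cum[lo - 1, ] else 0, length(s), k_all,
             byrow = TRUE)
    right <- matrix(tot, length(s), k_all, byrow = TRUE) - left
    nl <- rowSums(left); nr <- rowSums(right)
    h <- entropy_bits(tot)
    hl <- entropy_bits(left); hr <- entropy_bits(right)
    gain <- h - (nl * hl + nr * hr) / N
    best <- which.max(gain)
    k <- sum(tot > 0)
    k1 <- sum(left[best, ] > 0); k2 <- sum(right[best, ] > 0)
    delta <- log2(3^k - 2) -
      (k * h - k1 * hl[best] - k2 * hr[best])
    if (gain[best] <= (log2(N - 1) + delta) / N) return(invisible(NULL))
    sb <- s[best]
    cuts <<- c(cuts, (uv[sb] + uv[sb + 1]) / 2)
    recurse(lo, sb)
    recurse(sb + 1, hi)
    invisible(NULL)
  }
  recurse(1, nu)
  cuts <- sort(cuts)
  list(codes = findInterval(values, cuts) + 1L, cutpoints = cuts)
}

# Plug-in mutual information (nats) between two integer code vectors.
mi_codes <- function(a, b, na = max(a), nb = max(b)) {
  n <- length(a)
  joint <- tabulate((a - 1L) * nb + b, na * nb)
  pj <- joint / n
  pa <- tabulate(a, na) / n
  pb <- tabulate(b, nb) / n
  pprod <- as.vector(t(outer(pa, pb))) # match the (a-1)*nb + b layout
  ok <- pj > 0
  sum(pj[ok] * log(pj[ok] / pprod[ok]))
}

#' Rank features by mRMR
#'
#' Greedy minimum-redundancy maximum-relevance ranking with the MID
#' (mutual-information difference) criterion: at each step the feature
#' maximizing `I(f; y) - mean_{s in selected} I(f; s)` is added, with
#' mutual information estimated on MDL-discretized copies of the
#' features (plug-in estimator, natural log). Ties break by column
#' order.
#'
#' @param x Feature matrix or `feature_matrix`.
#' @param labels Class labels.
#' @param n Number of features to rank (default: all).
#' @return `data.frame` with columns `feature`, `score` (the MID score
#'   at selection time) and `relevance` (`I(f; y)`), in rank order.
#' @export
mrmr_rank <- function(x, labels, n = NULL) {
  if (inherits(x, "feature_matrix")) x <- x$values
  y <- as.integer(as_binary_labels(labels))
  p <- ncol(x)
  if (is.null(n)) n <- p
  stopifnot(n >= 1, n <= p)
  if (all(apply(x, 2, function(col) length(unique(col)) == 1)))
    stop("all features are constant; nothing to rank")
  codes <- matrix(1L, nrow(x), p)
  nbins <- integer(p)
  for (j in seq_len(p)) {
    d <- mdl_discretize(x[, j], y)
    codes[, j] <- d$codes
    nbins[j] <- max(d$codes)
  }
  rel <- vapply(seq_len(p), function(j)
    mi_codes(codes[, j], y, nbins[j], 2L), numeric(1))
  selected <- integer(0)
  score <- numeric(0)
  redsum <- numeric(p)
  remaining <- seq_len(p)
  for (step in seq_len(n)) {
    crit <- if (step == 1) rel[remaining]
            else rel[remaining] - redsum[remaining] / length(selected)
    pick <- remaining[which.max(crit)] # which.max: first max = column order
    selected <- c(selected, pick)
    score <- c(score, max(crit))
    remaining <- setdiff(remaining, pick)
    if (length(remaining) > 0 && step < n) {
      add <- vapply(remaining, function(j)
        mi_codes(codes[, j], codes[, pick], nbins[j], nbins[pick]),
        numeric(1))
      redsum[remaining] <- redsum[remaining] + add
    }
  }
  feats <- colnames(x)
  if (is.null(feats)) feats <- paste0("V", seq_len(p))
  data.frame(feature = feats[selected], score = score,
             relevance = rel[selected], stringsAsFactors = FALSE)
}

# Out-of-fold CV AUC of a random forest on (x, y).
rf_cv_auc <- function(x, y, folds, seed, num.trees = 100) {
  oof <- numeric(length(y))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    rf <- ranger::ranger(y = y[tr], x = x[tr, , drop = FALSE],
                         num.trees = num.trees, probability = TRUE,
                         seed = seed + f, num.threads = 1)
    oof[!tr] <- predict(rf, x[!tr, , drop = FALSE],
                        num.threads = 1)$predictions[, "positive"]
  }
  roc_auc(y, oof)
}

# Out-of-fold CV AUC of a linear SVM (decision values; ranking only).
svm_cv_auc <- function(x, y, folds) {
  oof <- numeric(length(y))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    m <- svm_fit(x[tr, , drop = FALSE], y[tr], kernel = "linear")
    oof[!tr] <- svm_decision(m, x[!tr, , drop = FALSE])
  }
  roc_auc(y, oof)
}

#' Forward incremental feature selection
#'
#' Walks the mRMR ranking, growing the feature set one candidate at a
#' time. A candidate is kept only if adding it does not decrease either
#' the random-forest or the SVM cross-validated AUC and strictly
#' increases at least one of them. The walk stops after `patience`
#' consecutive rejections (the AUC curve has passed its peak) or when
#' the ranking is exhausted.
#'
#' @param ranking `data.frame` from [mrmr_rank()] (or a character
#'   vector of feature names in rank order).
#' @param x Feature matrix or `feature_matrix` containing the ranked
#'   features.
#' @param labels Class labels.
#' @param cv A [cv_spec()] for the inner evaluation loop (default
#'   5-fold, a cheaper setting than the 10-fold model-level CV).
#' @param patience Consecutive rejections tolerated before stopping
#'   (default 20).
#' @return List of class `selection_result`: `ranking`, `trajectory`
#'   (one row per trial: set size tried, RF and SVM AUC, kept flag),
#'   `selected` (feature names) and `peak_index` (trajectory row of the
#'   best accepted mean AUC).
#' @export
forward_incremental_select <- function(ranking, x, labels,
                                       cv = cv_spec(n_folds = 5),
                                       patience = 20) {
  if (inherits(x, "feature_matrix")) x <- x$values
  if (is.data.frame(ranking)) ranking_names <- ranking$feature
  else ranking_names <- as.character(ranking)
  if (length(ranking_names) == 0) stop("empty ranking")
  missing_feats <- setdiff(ranking_names, colnames(x))
  if (length(missing_feats) > 0)
    stop("ranked feature(s) absent from the matrix: ",
         paste(head(missing_feats, 3), collapse = ", "))
  y <- as_binary_labels(labels)
  folds <- make_cv_folds(y, cv)
  selected <- character(0)
  cur_rf <- 0.5; cur_svm <- 0.5 # empty-set baseline: chance AUC
  traj <- vector("list", length(ranking_names))
  rejects <- 0L
  n_trials <- 0L
  for (cand in ranking_names) {
    n_trials <- n_trials + 1L
    feats <- c(selected, cand)
    xi <- x[, feats, drop = FALSE]
    auc_rf <- rf_cv_auc(xi, y, folds, seed = cv$seed + n_trials)
    auc_svm <- svm_cv_auc(xi, y, folds)
    keep <- auc_rf >= cur_rf && auc_svm >= cur_svm &&
      (auc_rf > cur_rf || auc_svm > cur_svm)
    traj[[n_trials]] <- data.frame(n_features = length(feats),
                                   auc_rf = auc_rf, auc_svm = auc_svm,
                                   feature = cand, kept = keep,
                                   stringsAsFactors = FALSE)
    if (keep) {
      selected <- feats
      cur_rf <- auc_rf; cur_svm <- auc_svm
      rejects <- 0L
    } else {
      rejects <- rejects + 1L
      if (rejects >= patience) break
    }
  }
  trajectory <- do.call(rbind, traj[seq_len(n_trials)])
  kept_rows <- which(trajectory$kept)
  peak_index <- if (length(kept_rows) > 0) {
    kept_rows[which.max((trajectory$auc_rf + trajectory$auc_svm)[kept_rows] / 2)]
  } else NA_integer_
  structure(list(ranking = ranking, trajectory = trajectory,
                 selected = selected, peak_index = peak_index),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("selection_result:", length(x$selected), "features selected after",
      nrow(x$trajectory), "trials\n")
  if (!is.na(x$peak_index))
    cat(sprintf("peak: RF AUC %.3f / SVM AUC %.3f at %d features\n",
                x$trajectory$auc_rf[x$peak_index],
                x$trajectory$auc_svm[x$peak_index],
                x$trajectory$n_features[x$peak_index]))
  invisible(x)
}

#' Serialize / load a selection result
#'
#' @param sel A `selection_result`.
#' @param path JSON output path.
#' @export
write_selection <- function(sel, path) {
  stopifnot(inherits(sel, "selection_result"))
  jsonlite::write_json(unclass(sel), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_selection
#' @export
read_selection <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$trajectory <- as.data.frame(obj$trajectory)
  obj$ranking <- as.data.frame(obj$ranking)
  structure(obj, class = "selection_result")
}

#' Out-of-bag permutation importance of a random forest
#'
#' For each feature, the mean over trees of the out-of-bag
#' correct-classification count minus the same count after permuting
#' the feature, divided by the tree's out-of-bag sample size. A feature
#' the forest never splits on scores exactly 0; a label-independent
#' feature scores near 0.
#'
#' @param model A [ranger::ranger()] classification forest trained with
#'   `keep.inbag = TRUE`.
#' @param x Feature matrix the model was trained on.
#' @param labels Class labels of `x`.
#' @param seed Seed for the permutations.
#' @return Named numeric vector of importances, one per feature.
#' @export
rf_permutation_importance <- function(model, x, labels, seed = 1) {
  if (!inherits(model, "ranger") || model$treetype != "Classification")
    stop("model must be a ranger classification forest")
  if (is.null(model$inbag.counts))
    stop("model has no out-of-bag bookkeeping; ",
         "train with keep.inbag = TRUE")
  y <- as.character(as_binary_labels(labels))
  inbag <- simplify2array(model$inbag.counts) # n x trees
  oob <- inbag == 0
  nb <- colSums(oob)
  if (any(nb == 0)) stop("some trees have no out-of-bag samples")
  pred_all <- function(xx) {
    p <- predict(model, xx, predict.all = TRUE,
                 num.threads = 1)$predictions
    matrix(model$forest$levels[p], nrow(xx))
  }
  base <- pred_all(x) == y
  base_counts <- colSums(base & oob)
  p <- ncol(x)
  imp <- numeric(p)
  for (j in seq_len(p)) {
    xp <- x
    xp[, j] <- with_local_seed(seed + j, sample(x[, j]))
    perm_counts <- colSums((pred_all(xp) == y) & oob)
    imp[j] <- mean((base_counts - perm_counts) / nb)
  }
  names(imp) <- colnames(x)
  imp
}
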