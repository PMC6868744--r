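# Small synthetic problem shared across the ensemble tests: three
# cheap feature clusters, strong sequence signal.
ens_fixture <- function(n = 40, seed = 12) {
  d <- generate_dataset(synth_config(n_pos = n, n_neg = n, seed = seed))
  fm <- assemble_feature_matrix(d$dataset, d$store,
                                blocks = c("AAC", "DISOPRED", "PSIPRED"))
  list(fm = fm, labels = d$dataset$label, data = d)
}

test_that("stage 1 returns calibrated out-of-fold scores for every model", {
  fx <- ens_fixture()
  base <- train_base_models(fx$fm, fx$labels, fx$fm$blocks,
                            cv = cv_spec(4, seed = 3))
  expect_equal(dim(base$oof), c(80, 6)) # 2 models x 3 feature sets
  expect_true(all(base$oof >= 0 & base$oof <= 1))
  expect_setequal(colnames(base$oof),
                  c("RF.AAC", "SVM.AAC", "RF.DISOPRED", "SVM.DISOPRED",
                    "RF.PSIPRED", "SVM.PSIPRED"))
  # separable synthetic data: every base model beats chance
  expect_true(all(base$aucs$rf_auc > 0.5))
  expect_true(all(base$aucs$svm_auc > 0.5))
  expect_true(all(base$aucs$svm_kernel %in%
                  c("linear", "polynomial", "radial")))
  expect_error(train_base_models(fx$fm, fx$labels, list(EMPTY = character(0)),
                                 cv = cv_spec(4)), "zero columns")
})

test_that("the meta network solves a separable stacking problem", {
  withr::with_seed(5, {
    y <- rep(c("positive", "negative"), each = 50)
    oof <- matrix(runif(100 * 6), 100, 6,
                  dimnames = list(NULL, paste0("m", 1:6)))
    oof[, 1] <- as.numeric(y == "positive")
    res <- cross_validate(oof, y, function(xtr, ytr) {
      meta <- train_meta_network(xtr, ytr, seed = 2)
      function(xte) sulfenR:::predict_meta(meta, xte)
    }, cv_spec(5, seed = 2))
    expect_gte(res$pooled$auc, 0.99)

    # constant inputs carry no signal: output constant-ish, AUC ~ 0.5
    flat <- matrix(0.5, 100, 6, dimnames = list(NULL, paste0("m", 1:6)))
    resf <- cross_validate(flat, y, function(xtr, ytr) {
      meta <- train_meta_network(xtr, ytr, seed = 2)
      function(xte) sulfenR:::predict_meta(meta, xte)
    }, cv_spec(5, seed = 2))
    expect_lt(abs(resf$pooled$auc - 0.5), 0.1)
    expect_error(train_meta_network(matrix(c(1, NA), 2, 1), c(1, 0)),
                 "non-finite")
  })
})

test_that("the hyperparameter grid search covers the 3 x 3 grid", {
  withr::with_seed(9, {
    y <- rep(c("positive", "negative"), each = 30)
    oof <- matrix(runif(60 * 4), 60, 4,
                  dimnames = list(NULL, paste0("m", 1:4)))
    oof[, 2] <- as.numeric(y == "positive") * 0.8 + runif(60) * 0.2
    grid <- meta_grid_search(oof, y, cv = cv_spec(4, seed = 1))
    expect_equal(dim(grid), c(3, 3))
    expect_equal(rownames(grid), c("units1", "units3", "units5"))
    expect_true(all(grid >= 0 & grid <= 1))
  })
})

test_that("stacked training, prediction and persistence are deterministic", {
  fx <- ens_fixture()
  model <- train_stacked(fx$fm, fx$labels, cv = cv_spec(4, seed = 6))
  expect_equal(length(model$base_models), 3)
  expect_equal(ncol(model$oof), 6)

  held <- generate_dataset(synth_config(n_pos = 25, n_neg = 25, seed = 77))
  fm_te <- assemble_feature_matrix(held$dataset, held$store,
                                   blocks = c("AAC", "DISOPRED", "PSIPRED"),
                                   norm = fx$fm$norm)
  p1 <- predict_stacked(model, fm_te)
  p2 <- predict_stacked(model, fm_te)
  expect_identical(p1$probability, p2$probability)
  expect_true(all(p1$probability > 0 & p1$probability < 1))

  # encoding route (dataset + store) agrees with the matrix route
  p3 <- predict_stacked(model, held$dataset, held$store)
  expect_equal(p3$probability, p1$probability)
  expect_true(all(c("protein_id", "position", "probability", "label") %in%
                  names(p3)))

  # stacking should not be materially worse than its best base model
  base_auc <- vapply(names(model$sets), function(s) {
    xs <- fm_te$values[, model$sets[[s]], drop = FALSE]
    max(roc_auc(held$dataset$label,
                sulfenR:::rf_score(model$base_models[[s]]$rf, xs)),
        roc_auc(held$dataset$label,
                sulfenR:::svm_score(model$base_models[[s]]$svm, xs)))
  }, numeric(1))
  expect_gte(roc_auc(held$dataset$label, p1$probability),
             max(base_auc) - 0.02)

  # persistence: bit-identical predictions after save/load
  f <- tempfile(fileext = ".rds")
  save_model(model, f)
  back <- load_model(f)
  expect_identical(predict_stacked(back, fm_te)$probability,
                   p1$probability)
  expect_true(all(unlist(back$sets) %in% colnames(fx$fm$values)))

  writeLines("not a model", f)
  expect_error(load_model(f), "model")
})

test_that("retraining with the same seed reproduces the model", {
  fx <- ens_fixture(n = 25, seed = 3)
  m1 <- train_stacked(fx$fm, fx$labels, cv = cv_spec(3, seed = 11))
  m2 <- train_stacked(fx$fm, fx$labels, cv = cv_spec(3, seed = 11))
  expect_identical(m1$oof, m2$oof)
  expect_equal(m1$meta$net$wts, m2$meta$net$wts)
})

test_that("prediction rejects matrices that do not match the manifest", {
  fx <- ens_fixture(n = 25, seed = 3)
  model <- train_stacked(fx$fm, fx$labels, cv = cv_spec(3, seed = 11))
  bad <- fx$fm$values[, 1:10]
  expect_error(sulfenR:::predict_stacked_scores(model, bad), "manifest")
})

test_that("out-of-fold stacking shows no leakage on label-shuffled data", {
  fx <- ens_fixture(n = 60, seed = 21)
  shuffled <- withr::with_seed(5, sample(fx$labels))
  model <- train_stacked(fx$fm, shuffled, cv = cv_spec(3, seed = 2))
  # the stacking inputs are out-of-fold, so they cannot encode the
  # shuffled labels: a meta-level CV on them sits near chance, whereas
  # in-sample base scores would memorize the labels and score ~1
  meta_cv <- cross_validate(model$oof, shuffled, function(xtr, ytr) {
    meta <- train_meta_network(xtr, ytr, seed = 3)
    function(xte) sulfenR:::predict_meta(meta, xte)
  }, cv_spec(3, seed = 3))
  expect_lt(meta_cv$pooled$auc, 0.75)
  in_sample <- vapply(names(model$sets), function(s)
    roc_auc(shuffled, sulfenR:::rf_score(
      model$base_models[[s]]$rf,
      fx$fm$values[, model$sets[[s]], drop = FALSE])), numeric(1))
  expect_gt(max(in_sample), 0.9) # what leakage would have fed the meta
})
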