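# Independent MI oracle used against mrmr_rank: entropies from table().
mi_table <- function(a, b) {
  H <- function(t) { p <- t / sum(t); -sum(p[p > 0] * log(p[p > 0])) }
  H(table(a)) + H(table(b)) - H(table(paste(a, b)))
}

test_that("MDL discretization cuts separable features and spares noise", {
  y <- rep(c("A", "B"), each = 30)
  v <- rep(c(0, 1), each = 30)
  d <- mdl_discretize(v, y)
  expect_equal(length(d$cutpoints), 1)
  expect_gt(d$cutpoints, 0)
  expect_lt(d$cutpoints, 1)
  expect_equal(d$codes, rep(c(1L, 2L), each = 30))

  withr::with_seed(13, {
    noise <- runif(200)
    yn <- sample(c("A", "B"), 200, TRUE)
    expect_equal(length(mdl_discretize(noise, yn)$cutpoints), 0)
  })

  const <- mdl_discretize(rep(3.3, 50), y[1:50])
  expect_equal(const$codes, rep(1L, 50))
  expect_equal(length(const$cutpoints), 0)
})

test_that("mRMR ranks relevance first and penalizes redundant copies", {
  withr::with_seed(2, {
    y <- rep(c("positive", "negative"), each = 50)
    x <- cbind(f1 = as.numeric(y == "positive"), f2 = runif(100))
    expect_equal(mrmr_rank(x, y)$feature[1], "f1")

    # f1 strongly informative, f2 an exact copy, f3 weakly informative:
    # redundancy drives the copy below the weak independent feature
    f1 <- as.numeric(y == "positive") + rnorm(100, 0, 0.25)
    f3 <- as.numeric(y == "positive") * 0.6 + rnorm(100, 0, 1)
    x3 <- cbind(f1 = f1, f2 = f1, f3 = f3)
    r <- mrmr_rank(x3, y)
    expect_equal(r$feature, c("f1", "f3", "f2"))

    expect_equal(nrow(mrmr_rank(x3, y, n = 1)), 1)
    expect_error(mrmr_rank(cbind(k = rep(1, 100)), y), "constant")
  })
})

test_that("mRMR step 1 is the max-marginal-MI feature (oracle check)", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      y <- sample(c("positive", "negative"), 120, TRUE)
      x <- matrix(rnorm(120 * 8), 120, 8,
                  dimnames = list(NULL, paste0("g", 1:8)))
      x[, 3] <- x[, 3] + (y == "positive") * runif(1, 1, 2.5)
      top <- mrmr_rank(x, y, n = 1)$feature
      mis <- vapply(seq_len(ncol(x)), function(j)
        mi_table(mdl_discretize(x[, j], y)$codes, y), numeric(1))
      expect_equal(top, colnames(x)[which.max(mis)])
    }
  })
})

test_that("forward selection keeps the separating feature once and stops", {
  dat <- toy_features(n = 80, p = 10, seed = 9, signal = 3)
  r <- mrmr_rank(dat$x, dat$y)
  sel <- forward_incremental_select(r, dat$x, dat$y,
                                    cv = cv_spec(4, seed = 1),
                                    patience = 4)
  expect_true("f1" %in% sel$selected)
  expect_lte(length(sel$selected), 3)
  expect_equal(sel$trajectory$n_features[1], 1)
  expect_true(all(c("auc_rf", "auc_svm", "kept") %in%
                  names(sel$trajectory)))

  # an exact duplicate of the informative feature is never kept twice
  x2 <- cbind(dat$x[, "f1", drop = FALSE], f1b = dat$x[, "f1"],
              dat$x[, 2:4])
  sel2 <- forward_incremental_select(c("f1", "f1b"), x2, dat$y,
                                     cv = cv_spec(4, seed = 1),
                                     patience = 5)
  expect_equal(sel2$selected, "f1")
})

test_that("selection results are deterministic and serializable", {
  dat <- toy_features(n = 60, p = 6, seed = 3)
  r <- mrmr_rank(dat$x, dat$y)
  s1 <- forward_incremental_select(r, dat$x, dat$y,
                                   cv = cv_spec(3, seed = 7), patience = 3)
  s2 <- forward_incremental_select(r, dat$x, dat$y,
                                   cv = cv_spec(3, seed = 7), patience = 3)
  expect_identical(s1$trajectory, s2$trajectory)
  f <- tempfile(fileext = ".json")
  write_selection(s1, f)
  back <- read_selection(f)
  expect_equal(back$selected, s1$selected)
  expect_equal(back$trajectory$auc_rf, s1$trajectory$auc_rf,
               tolerance = 1e-9)
})

test_that("OOB permutation importance is 0 for unused features and ranks the label top", {
  withr::with_seed(17, {
    n <- 200
    y <- factor(rep(c("positive", "negative"), each = n / 2),
                levels = c("positive", "negative"))
    x <- cbind(lab = as.numeric(y == "positive"),
               n1 = rnorm(n), n2 = rnorm(n), flat = rep(1, n))
    rf <- ranger::ranger(y = y, x = x, num.trees = 60, keep.inbag = TRUE,
                         seed = 4, num.threads = 1)
    imp <- rf_permutation_importance(rf, x, y, seed = 11)
    expect_identical(unname(imp["flat"]), 0) # never split on -> exactly 0
    expect_gt(imp["lab"], max(imp[c("n1", "n2")]))

    rf_no_inbag <- ranger::ranger(y = y, x = x, num.trees = 20, seed = 4,
                                  num.threads = 1)
    expect_error(rf_permutation_importance(rf_no_inbag, x, y),
                 "keep.inbag")
  })
})
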