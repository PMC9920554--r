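test_that("fold assignment partitions samples into near-equal folds", {
  f <- make_folds(10, 5, seed = 1)
  expect_equal(as.integer(table(f)), rep(2L, 5))
  expect_identical(make_folds(10, 5, seed = 1), make_folds(10, 5, seed = 1))
  for (seed in 1:10) {
    f11 <- make_folds(11, 5, seed = seed)
    expect_equal(sort(as.integer(table(f11))), c(2L, 2L, 2L, 2L, 3L))
  }
  expect_error(make_folds(4, 5), "must be >=")
  # stratified variant still partitions evenly
  y <- runif(23)
  fs <- make_folds(23, 5, seed = 2, stratify_y = y)
  expect_true(max(table(fs)) - min(table(fs)) <= 1)
})

test_that("metrics reproduce the hand-worked example and their identity", {
  y <- c(1, 2, 3, 4); yhat <- c(1, 2, 3, 5)
  expect_equal(r_squared(y, yhat), 0.8)
  expect_equal(rmse(y, yhat), 0.5)
  expect_equal(rpiq(y, yhat), 3.0)

  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 4)), 0)
  expect_equal(rmse(y, y), 0)
  expect_equal(rmse(y, y + 1), 1)
  expect_error(r_squared(rep(2, 4), y), "constant")
  expect_error(rpiq(y, y), "perfect fit")
  expect_equal(rpiq(rep(3, 4), c(3, 3, 3, 4)), 0)  # zero IQR

  # R2 = 1 - RMSE^2 * N / SS_tot on any vectors
  for (seed in 1:10) {
    withr::with_seed(seed, {
      y <- rnorm(25); yhat <- y + rnorm(25, sd = 0.5)
    })
    expect_equal(r_squared(y, yhat),
                 1 - rmse(y, yhat)^2 * 25 / sum((y - mean(y))^2))
  }
})

test_that("a degenerate single-point grid reduces nested CV to plain CV", {
  lib <- one_band_library(n = 50)
  rep1 <- nested_cv(lib, "Ref", "PLS", seed = 9, grid = data.frame(ncomp = 2))
  # manual plain 5-fold CV with the same derived seeds
  treated <- apply_chain("Ref", lib)
  X <- treated$spectra; y <- treated$samples$brix
  outer <- make_folds(nrow(X), 5, derive_seed(9, "outer-folds"))
  for (e in 1:5) {
    tr <- outer != e
    m <- grape_model("PLS", X[tr, ], y[tr], list(ncomp = 2),
                     seed = derive_seed(9, "refit", e))
    expect_equal(rep1$folds[[e]]$predictions$y_pred,
                 unname(predict(m, X[!tr, , drop = FALSE])))
  }
  expect_equal(rep1$mean_rmse, mean(rep1$metrics$rmse))
})

test_that("nested CV recovers a noiseless one-band signal with PLS", {
  lib <- one_band_library(n = 60)
  report <- nested_cv(lib, "Ref", "PLS", seed = 4,
                      grid = data.frame(ncomp = 1:15))
  expect_gte(report$mean_r2, 0.999)
})

test_that("fold-mean metrics equal recomputation from stored predictions", {
  lib <- one_band_library(n = 50)
  report <- nested_cv(lib, "Ref", "SVR", seed = 2,
                      grid = expand.grid(cost = c(1, 32), epsilon = 0.05))
  per_fold <- vapply(report$folds, function(f) {
    rmse(f$predictions$y_true, f$predictions$y_pred)
  }, numeric(1))
  expect_equal(report$mean_rmse, mean(per_fold))
  expect_equal(report$metrics$rmse, unname(per_fold))
  # every sample appears in exactly one test fold
  ids <- unlist(lapply(report$folds, function(f) f$predictions$sample_id))
  expect_setequal(ids, lib$samples$sample_id)
  expect_false(any(duplicated(ids)))
})

test_that("external test folds never intersect the data the internal loop saw", {
  lib <- one_band_library(n = 50)
  for (fam in c("PLS", "RF")) {
    gr <- if (fam == "PLS") data.frame(ncomp = 1:3)
          else expand.grid(ntree = 50, max_features = "sqrt",
                           stringsAsFactors = FALSE)
    report <- nested_cv(lib, "Ref", fam, seed = 5, grid = gr)
    for (f in report$folds) {
      expect_length(intersect(f$test_idx, f$calib_idx), 0)
      expect_setequal(union(f$test_idx, f$calib_idx), seq_len(n_samples(lib)))
    }
  }
})

test_that("best pre-treatment selection uses the internal criterion with tie rules", {
  fake <- function(chain, internal, test_rmse = 1) {
    structure(list(variety = "Syrah", family = "PLS", chain = chain,
                   mean_r2 = 0.9, mean_rmse = test_rmse, mean_rpiq = 4,
                   mean_internal_rmse = internal),
              class = "cv_report")
  }
  # single candidate
  one <- select_best(list(fake("Abs", 2.0)))
  expect_equal(one$chain, "Abs")
  # lower internal RMSE wins even with worse test RMSE
  two <- select_best(list(fake("Abs", 2.0, test_rmse = 3), fake("CR", 2.5, test_rmse = 1)))
  expect_equal(two$chain, "Abs")
  # tie -> fewer steps
  tie <- select_best(list(fake("Ref+SG1", 2.0), fake("Ref", 2.0)))
  expect_equal(tie$chain, "Ref")
  # tie at equal depth -> lexicographic
  tie2 <- select_best(list(fake("CR", 2.0), fake("Abs", 2.0)))
  expect_equal(tie2$chain, "Abs")
})

test_that("nested CV is reproducible end to end", {
  lib <- one_band_library(n = 50)
  r1 <- nested_cv(lib, "Abs", "PLS", seed = 31, grid = data.frame(ncomp = 1:3))
  r2 <- nested_cv(lib, "Abs", "PLS", seed = 31, grid = data.frame(ncomp = 1:3))
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$folds[[3]]$predictions, r2$folds[[3]]$predictions)
})
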