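test_that("mutual information vanishes for independent pairs and finds dependence", {
  # independence: average over seeds stays near zero
  mis <- sapply(1:30, function(seed) {
    withr::with_seed(seed, {
      x <- rnorm(120); y <- rnorm(120)
    })
    grapespec:::ksg_mi(x, y, k = 3)
  })
  expect_lte(mean(pmax(mis, 0)), 0.05)

  # deterministic monotone dependence: the coupled band is the argmax
  withr::with_seed(2, {
    X <- matrix(rnorm(80 * 10), 80, 10)
    y <- exp(X[, 6])
  })
  prof <- mutual_information_profile(X, y, seed = 1)
  expect_equal(which.max(prof$score), 6)
  expect_true(all(prof$score >= 0))

  # constant band scores zero and is flagged
  X[, 2] <- 1
  prof2 <- mutual_information_profile(X, y, seed = 1)
  expect_equal(prof2$score[2], 0)
  expect_equal(attr(prof2, "constant_bands"), 2L)
})

test_that("mutual information matches the Gaussian closed form", {
  rho <- 0.9
  withr::with_seed(7, {
    x <- rnorm(2000)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(2000)
  })
  expect_equal(grapespec:::ksg_mi(x, y, k = 3), -0.5 * log(1 - rho^2),
               tolerance = 0.1 / 0.83)
})

test_that("mutual information is invariant to monotone transforms of y", {
  withr::with_seed(11, {
    x <- rnorm(2000)
    y <- x + rnorm(2000, sd = 0.5)
  })
  mi1 <- grapespec:::ksg_mi(x, y)
  mi2 <- grapespec:::ksg_mi(x, exp(y / 2))
  expect_equal(mi1, mi2, tolerance = 0.15)
})

test_that("VIP scores are normalized and match the textbook formula", {
  withr::with_seed(3, {
    X <- matrix(rnorm(40 * 12), 40, 12)
    y <- 2 * X[, 1] + X[, 7] + rnorm(40, sd = 0.3)
  })
  m <- grape_model("PLS", X, y, list(ncomp = 4), seed = 1)
  v <- vip_scores(m)
  expect_equal(mean(v$score^2), 1, tolerance = 1e-9)
  expect_gt(v$score[1], 1)  # informative bands stand out

  # single-feature model: normalization forces VIP = 1
  m1 <- grape_model("PLS", X[, 1, drop = FALSE], y, list(ncomp = 1), seed = 1)
  expect_equal(vip_scores(m1)$score, 1)

  # hand evaluation of the VIP definition from the fitted pieces
  f <- m$fit
  ssy <- f$q^2 * colSums(f$T^2)
  byhand <- sqrt(ncol(X) * as.vector(f$W^2 %*% ssy) / sum(ssy))
  expect_equal(v$score, byhand)
  expect_error(vip_scores(grape_model("RF", X, y, list(ntree = 50), seed = 1)),
               "PLS")
})

test_that("VIP scores agree with an independent implementation", {
  skip_if_not_installed("mixOmics")
  withr::with_seed(13, {
    X <- matrix(rnorm(50 * 8), 50, 8)
    colnames(X) <- paste0("b", 1:8)
    y <- X[, 2] - 0.5 * X[, 5] + rnorm(50, sd = 0.2)
  })
  m <- grape_model("PLS", X, y, list(ncomp = 3), seed = 1)
  ref <- mixOmics::pls(scale(X), y, ncomp = 3, mode = "regression", scale = FALSE)
  expect_equal(unname(vip_scores(m)$score),
               unname(mixOmics::vip(ref)[, 3]), tolerance = 1e-6)
})

test_that("impurity importance is a simplex over the bands", {
  withr::with_seed(4, {
    X <- matrix(rnorm(80 * 6), 80, 6)
    X[, 3] <- 0.5  # constant band is never split on
    y <- 3 * X[, 1] + rnorm(80, sd = 0.2)
  })
  m <- grape_model("RF", X, y, list(ntree = 100, max_features = "max"), seed = 1)
  g <- gini_importance(m)
  expect_equal(sum(g$score), 1, tolerance = 1e-9)
  expect_true(all(g$score >= 0))
  expect_equal(g$score[3], 0)
  expect_gt(g$score[1], 0.5)  # the single informative band dominates
  expect_error(gini_importance(grape_model("PLS", X, y, list(ncomp = 2), seed = 1)),
               "random-forest")
})

test_that("sampled SAGE matches exhaustive Shapley enumeration on a 3-feature toy", {
  withr::with_seed(5, {
    X_bg <- matrix(rnorm(20 * 3), 20, 3)
    X_eval <- matrix(rnorm(12 * 3), 12, 3)
  })
  beta <- c(2, -1, 0.5)
  fun <- function(X) as.vector(X %*% beta)
  y_eval <- fun(X_eval) + withr::with_seed(6, rnorm(12, sd = 0.1))
  est <- sage_values(fun, X_bg, X_eval, y_eval, n_permutations = 300, seed = 8)
  oracle <- exact_sage(fun, X_bg, X_eval, y_eval)
  for (j in 1:3) {
    expect_lt(abs(est$score[j] - oracle[j]), 3 * est$stderr[j] + 1e-8)
  }
})

test_that("SAGE satisfies the null-player and efficiency properties", {
  withr::with_seed(10, {
    X_bg <- matrix(rnorm(30 * 4), 30, 4)
    X_eval <- matrix(rnorm(15 * 4), 15, 4)
  })
  fun <- function(X) as.vector(X %*% c(1.5, 0, -2, 0))  # features 2 and 4 ignored
  y_eval <- fun(X_eval)
  est <- sage_values(fun, X_bg, X_eval, y_eval, n_permutations = 200, seed = 3)
  expect_lt(abs(est$score[2]), 3 * est$stderr[2] + 1e-8)
  expect_lt(abs(est$score[4]), 3 * est$stderr[4] + 1e-8)
  # efficiency: scores sum exactly to baseline loss - full-model loss
  expect_equal(sum(est$score),
               attr(est, "baseline_loss") - attr(est, "full_loss"),
               tolerance = 1e-10)
  expect_error(sage_values(fun, X_bg, X_eval, y_eval, n_permutations = 0),
               "n_permutations")
})

test_that("SAGE Monte-Carlo error shrinks like one over sqrt(permutations)", {
  withr::with_seed(14, {
    X_bg <- matrix(rnorm(20 * 3), 20, 3)
    X_eval <- matrix(rnorm(10 * 3), 10, 3)
  })
  fun <- function(X) as.vector(X %*% c(1, -1, 2))
  y_eval <- fun(X_eval)
  ses <- vapply(c(25, 100, 400), function(np) {
    mean(sage_values(fun, X_bg, X_eval, y_eval, n_permutations = np,
                     seed = 5)$stderr)
  }, numeric(1))
  expect_equal(ses[1] / ses[2], 2, tolerance = 0.5)
  expect_equal(ses[2] / ses[3], 2, tolerance = 0.5)
  expect_true(all(diff(ses) < 0))
})

test_that("mean ranking averages fold profiles and their ranks", {
  mk <- function(s) grapespec:::importance_profile("VIP", c(500, 510), s, fold = 1)
  ident <- mean_rank(list(mk(c(2, 1)), mk(c(2, 1)), mk(c(2, 1))))
  expect_equal(ident$score, c(2, 1))
  expect_equal(ident$mean_rank, c(1, 2))

  sym <- mean_rank(list(mk(c(1, 0)), mk(c(0, 1))))
  expect_equal(sym$score, c(0.5, 0.5))
  expect_equal(sym$mean_rank, c(1.5, 1.5))

  withr::with_seed(6, {
    profs <- lapply(1:5, function(i) {
      grapespec:::importance_profile("MI", seq(400, 440, 10), runif(5), fold = i)
    })
  })
  avg <- mean_rank(profs)
  byhand <- rowMeans(sapply(profs, `[[`, "score"))
  expect_equal(avg$score, byhand)
  # averaging cannot shrink the nonzero support
  expect_gte(sum(avg$score > 0), max(sapply(profs, function(p) sum(p$score > 0))))

  bad <- grapespec:::importance_profile("MI", c(400, 450), runif(2))
  expect_error(mean_rank(list(profs[[1]], bad)), "mismatched")
  expect_error(mean_rank(list(profs[[1]], mk(c(1, 2)))), "mix")
})
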