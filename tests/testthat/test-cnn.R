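test_that("configuration validation enforces the search-space ranges", {
  expect_error(cnn_config(kernel = 4), "kernel")
  expect_error(cnn_config(filters = 9), "filters")
  expect_error(cnn_config(lr = 0.5), "learning rate")
  expect_error(cnn_config(batch_size = 5), "batch_size")
  expect_error(cnn_config(n_conv = 4), "n_conv")
  cfg <- cnn_config(n_conv = 2, filters = c(8, 12))
  expect_identical(cfg$filters, c(8L, 12L))
})

test_that("sampled configurations always lie inside the search space", {
  for (seed in 1:40) {
    cfg <- withr::with_seed(seed, grapespec:::sample_cnn_config())
    expect_s3_class(cfg, "cnn_config")  # constructor re-validates every field
    expect_true(cfg$lr >= 1e-4 && cfg$lr <= 1e-2)
  }
})

test_that("parameter count matches hand-derived arithmetic", {
  # 216 bands, 1 conv (8 filters, kernel 3), 1 dense of 8:
  # conv 3*1*8+8 = 32; flatten 214*8 = 1712; dense 1712*8+8 = 13704; out 8+1
  cfg <- cnn_config(n_conv = 1, filters = 8, kernel = 3, n_dense = 1, units = 8)
  expect_equal(cnn_param_count(cfg, 216), 32 + 13704 + 9)
  # with BN and pooling: conv 32 + bn 16; pooled length (216-2) %/% 2 = 107
  cfg2 <- cnn_config(n_conv = 1, filters = 8, kernel = 3, batch_norm = TRUE,
                     max_pool = TRUE, n_dense = 1, units = 8)
  expect_equal(cnn_param_count(cfg2, 216), 32 + 16 + (107 * 8 * 8 + 8) + 9)
  # counted parameters all exist in the built network
  layers <- withr::with_seed(1, grapespec:::cnn_build_layers(cfg2, 216))
  got <- sum(vapply(layers, function(ly) {
    length(ly[["W"]]) + length(ly[["b"]]) + length(ly[["gamma"]]) + length(ly[["beta"]])
  }, numeric(1)))
  expect_equal(got, cnn_param_count(cfg2, 216))
})

test_that("backpropagated gradients match finite differences", {
  cfg <- cnn_config(standardize = "none", n_conv = 2, filters = c(8, 8),
                    kernel = 3, batch_norm = TRUE, max_pool = TRUE,
                    n_dense = 1, units = 8, batch_size = 4, lr = 1e-3)
  p <- 17; B <- 4
  withr::with_seed(9, {
    layers <- grapespec:::cnn_build_layers(cfg, p)
    X <- matrix(rnorm(B * p), B, p)
    y <- rnorm(B)
  })
  loss_of <- function(layers) {
    out <- grapespec:::cnn_forward(layers, X, training = TRUE)$out
    mean((out - y)^2)
  }
  fw <- grapespec:::cnn_forward(layers, X, training = TRUE)
  dout <- matrix(2 * (fw$out - y) / B, B, 1)
  grads <- grapespec:::cnn_backward(layers, fw$cache, dout)
  eps <- 1e-6
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (nm in names(g)) {
      target <- layers[[i]][[nm]]
      probe <- withr::with_seed(i, sample(length(target), min(4, length(target))))
      for (j in probe) {
        lp <- layers; lp[[i]][[nm]][j] <- lp[[i]][[nm]][j] + eps
        lm_ <- layers; lm_[[i]][[nm]][j] <- lm_[[i]][[nm]][j] - eps
        fd <- (loss_of(lp) - loss_of(lm_)) / (2 * eps)
        expect_equal(g[[nm]][j], fd, tolerance = 1e-4,
                     label = sprintf("layer %d %s[%d] analytic", i, nm, j))
      }
    }
  }
})

test_that("training fits a noiseless linear target well within budget", {
  withr::with_seed(3, {
    X <- matrix(runif(500 * 24, 0, 1), 500, 24)
    y <- 10 + 8 * X[, 5] - 6 * X[, 17]
  })
  cfg <- cnn_config(standardize = "zscore", n_conv = 1, filters = 16, kernel = 3,
                    n_dense = 1, units = 32, batch_size = 6, lr = 8e-3)
  fit <- cnn_train(cfg, X, y, seed = 2, max_epochs = 200)
  expect_lt(fit$val_rmse, 0.1 * sd(y))
})

test_that("batch-norm inference uses running statistics and stays finite", {
  withr::with_seed(4, {
    X <- matrix(rnorm(60 * 15), 60, 15)
    y <- X[, 4] + rnorm(60, sd = 0.1)
  })
  cfg <- cnn_config(n_conv = 1, filters = 8, kernel = 3, batch_norm = TRUE,
                    n_dense = 1, units = 8, lr = 3e-3)
  fit <- cnn_train(cfg, X, y, seed = 1, max_epochs = 15)
  pred <- cnn_predict(fit, X)
  expect_true(all(is.finite(pred)))
  one_row <- cnn_predict(fit, X[1, , drop = FALSE])  # eval mode works at B = 1
  expect_equal(one_row, pred[1])
})

test_that("hyperband is deterministic and degenerates gracefully", {
  withr::with_seed(8, {
    X <- matrix(rnorm(50 * 12), 50, 12)
    y <- 15 + 2 * X[, 3] + rnorm(50, sd = 0.2)
  })
  # budget of one configuration: that configuration is returned
  one <- hyperband_cnn(X, y, seed = 21, n_configs = 1, max_resource = 5)
  expect_identical(one$best_config,
                   withr::with_seed(derive_seed(21, "hb-config", 1),
                                    grapespec:::sample_cnn_config()))
  # same master seed -> identical choice; different seed is allowed to differ
  a <- hyperband_cnn(X, y, seed = 33, n_configs = 3, max_resource = 6)
  b <- hyperband_cnn(X, y, seed = 33, n_configs = 3, max_resource = 6)
  expect_identical(a$best_config, b$best_config)
  expect_identical(a$leaderboard, b$leaderboard)
  expect_true(all(diff(unique(a$leaderboard$epochs)) > 0))  # budgets grow
  expect_error(hyperband_cnn(X, y, seed = 1, n_configs = 0), "at least one")
})
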