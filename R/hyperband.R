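#' Hyperband search over CNN configurations
#'
#' Successive-halving search over the CNN hyperparameter space: sample
#' `n_configs` configurations, train each for a small epoch budget, keep
#' the best `1/eta` fraction, triple (by default) the budget, and repeat
#' until one configuration trains at the full budget. Configurations are
#' scored by RMSE on a fixed internal validation split carved (seeded)
#' from the calibration data; early stopping remains active inside each
#' training run. The whole search is deterministic given `seed`.
#'
#' @param X,y calibration spectra matrix and Brix vector.
#' @param seed integer master seed for sampling, splitting and training.
#' @param n_configs number of configurations to sample (>= 1).
#' @param max_resource maximum epoch budget (the final rung).
#' @param eta halving (reduction) factor.
#' @param val_frac fraction of calibration rows held out as the internal
#'   validation split.
#' @param patience early-stopping patience passed to [cnn_train()].
#' @return a list with `best_config`, `best_fit` (the model trained at the
#'   final rung), `best_val_rmse` (internal-validation RMSE in Brix),
#'   `leaderboard` (a data frame of all evaluated (config, rung, epochs,
#'   val_rmse) rows) and the validation row indices `val_idx`.
#' @export
hyperband_cnn <- function(X, y, seed = 1L, n_configs = 8L, max_resource = 200L,
                          eta = 3, val_frac = 0.2, patience = 40L) {
  X <- as.matrix(X)
  check_that(n_configs >= 1, "budget too small: need at least one configuration")
  n <- nrow(X)
  val_idx <- with_seed(derive_seed(seed, "hb-split"), {
    sample(n, max(2L, round(val_frac * n)))
  })
  X_val <- X[val_idx, , drop = FALSE]; y_val <- y[val_idx]
  X_tr <- X[-val_idx, , drop = FALSE]; y_tr <- y[-val_idx]
  configs <- lapply(seq_len(n_configs), function(i) {
    with_seed(derive_seed(seed, "hb-config", i), sample_cnn_config())
  })
  alive <- seq_len(n_configs)
  n_rungs <- if (n_configs == 1) 0L else ceiling(log(n_configs, eta))
  leaderboard <- NULL
  fits <- vector("list", n_configs)
  for (rung in 0:n_rungs) {
    epochs <- max(1L, floor(max_resource / eta^(n_rungs - rung)))
    scores <- vapply(alive, function(i) {
      fit <- tryCatch(
        cnn_train(configs[[i]], X_tr, y_tr,
                  seed = derive_seed(seed, "hb-train", i, rung),
                  X_val = X_val, y_val = y_val,
                  max_epochs = epochs, patience = patience),
        error = function(e) e)   # e.g. config too deep for the input length
      if (inherits(fit, "error")) return(Inf)
      fits[[i]] <<- fit
      fit$val_rmse
    }, numeric(1))
    leaderboard <- rbind(leaderboard,
                         data.frame(config = alive, rung = rung,
                                    epochs = epochs, val_rmse = scores))
    keep <- max(1L, ceiling(length(alive) / eta))
    alive <- alive[order(scores)][seq_len(keep)]
    if (length(alive) == 1 && rung == n_rungs) break
  }
  best <- alive[1]
  list(best_config = configs[[best]], best_fit = fits[[best]],
       best_val_rmse = leaderboard$val_rmse[leaderboard$config == best &
                                            leaderboard$rung == n_rungs],
       leaderboard = leaderboard, val_idx = val_idx)
}
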