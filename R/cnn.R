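# A compact 1-D convolutional network engine for spectral regression.
#
# Architecture: per-band input standardization -> [conv1d (+ optional
# batch-norm) -> ReLU (-> optional max-pool, window 2)] x L -> flatten ->
# dense stack with ReLU and an L2 penalty (0.0004) on dense weights ->
# single linear output. Trained with Adam on mean squared error, a step
# decay halving the learning rate every 60 epochs, early stopping on
# validation loss (patience 40, best weights restored), max 200 epochs.
#
# Convolutions use valid padding and are computed by an im2col/matrix
# multiplication; batches are small (4-8), so everything stays in plain
# matrix algebra. All randomness (initialization, validation carve-out,
# epoch shuffling) is governed by one seed, making training bit-reproducible.

#' CNN configuration
#'
#' Validates one point of the CNN search space:
#' input standardization in \{none, min-max, standard-score\}; 1--3 conv
#' layers with 8--32 filters (even counts) and kernel size in \{3, 5, 7\};
#' optional batch normalization and optional max pooling (window 2,
#' i.e. halving) after each conv layer; 1--3 fully connected layers of
#' 8--64 units (even counts); batch size in \{4, 6, 8\}; Adam learning
#' rate in \[1e-4, 1e-2\].
#'
#' @param standardize one of `"none"`, `"minmax"` (per-band to \[-1, 1\]),
#'   `"zscore"` (per-band standard score). Statistics are computed on the
#'   training partition only.
#' @param n_conv number of convolutional layers (1--3).
#' @param filters integer vector of filters per conv layer (recycled to
#'   `n_conv`), each in \{8, 10, ..., 32\}.
#' @param kernel kernel size, one of 3, 5, 7.
#' @param batch_norm logical: batch normalization after each conv layer.
#' @param max_pool logical: max pooling (window 2) after each conv layer.
#' @param n_dense number of fully connected layers (1--3), excluding the
#'   final inference layer.
#' @param units integer vector of units per dense layer (recycled), each
#'   in \{8, 10, ..., 64\}.
#' @param batch_size one of 4, 6, 8.
#' @param lr Adam learning rate in \[1e-4, 1e-2\].
#' @return a validated `cnn_config` object.
#' @export
cnn_config <- function(standardize = "zscore", n_conv = 1, filters = 16,
                       kernel = 3, batch_norm = FALSE, max_pool = FALSE,
                       n_dense = 1, units = 32, batch_size = 6, lr = 1e-3) {
  check_that(standardize %in% c("none", "minmax", "zscore"),
             "standardize must be one of none/minmax/zscore")
  check_that(n_conv %in% 1:3, "n_conv must be in {1,2,3}")
  filters <- rep_len(as.integer(filters), n_conv)
  check_that(all(filters %in% seq(8L, 32L, 2L)), "filters must be in {8,10,...,32}")
  check_that(kernel %in% c(3, 5, 7), "kernel size must be in {3,5,7}")
  check_that(is.logical(batch_norm) && is.logical(max_pool),
             "batch_norm and max_pool must be logical")
  check_that(n_dense %in% 1:3, "n_dense must be in {1,2,3}")
  units <- rep_len(as.integer(units), n_dense)
  check_that(all(units %in% seq(8L, 64L, 2L)), "units must be in {8,10,...,64}")
  check_that(batch_size %in% c(4, 6, 8), "batch_size must be in {4,6,8}")
  check_that(lr >= 1e-4 && lr <= 1e-2, "learning rate must be in [1e-4, 1e-2]")
  structure(list(standardize = standardize, n_conv = as.integer(n_conv),
                 filters = filters, kernel = as.integer(kernel),
                 batch_norm = batch_norm, max_pool = max_pool,
                 n_dense = as.integer(n_dense), units = units,
                 batch_size = as.integer(batch_size), lr = lr),
            class = "cnn_config")
}

#' @export
print.cnn_config <- function(x, ...) {
  cat(sprintf(
    "cnn_config: std=%s | conv x%d (filters %s, kernel %d%s%s) | dense x%d (units %s) | batch %d, lr %.2g\n",
    x$standardize, x$n_conv, paste(x$filters, collapse = "/"), x$kernel,
    if (x$batch_norm) ", BN" else "", if (x$max_pool) ", pool" else "",
    x$n_dense, paste(x$units, collapse = "/"), x$batch_size, x$lr))
  invisible(x)
}

# Sample one configuration uniformly from the search space (uses the
# caller's RNG stream; learning rate is log-uniform).
sample_cnn_config <- function() {
  n_conv <- sample(1:3, 1)
  n_dense <- sample(1:3, 1)
  cnn_config(
    standardize = sample(c("none", "minmax", "zscore"), 1),
    n_conv = n_conv,
    filters = sample(seq(8L, 32L, 2L), n_conv, replace = TRUE),
    kernel = sample(c(3L, 5L, 7L), 1),
    batch_norm = sample(c(FALSE, TRUE), 1),
    max_pool = sample(c(FALSE, TRUE), 1),
    n_dense = n_dense,
    units = sample(seq(8L, 64L, 2L), n_dense, replace = TRUE),
    batch_size = sample(c(4L, 6L, 8L), 1),
    lr = 10^stats::runif(1, -4, -2)
  )
}

# --- layer construction --------------------------------------------------

cnn_build_layers <- function(config, n_features) {
  layers <- list()
  L <- n_features; C <- 1L
  for (i in seq_len(config$n_conv)) {
    k <- config$kernel; f <- config$filters[i]
    check_that(L >= k, "input too short (%d) for conv kernel %d at layer %d", L, k, i)
    fan_in <- k * C
    layers[[length(layers) + 1]] <- list(
      type = "conv", k = k, C_in = C, C_out = f,
      W = matrix(stats::rnorm(fan_in * f, sd = sqrt(2 / fan_in)), fan_in, f),
      b = numeric(f))
    L <- L - k + 1L; C <- f
    if (config$batch_norm) {
      layers[[length(layers) + 1]] <- list(
        type = "bn", C = f, gamma = rep(1, f), beta = numeric(f),
        rmean = numeric(f), rvar = rep(1, f), eps = 1e-5, momentum = 0.9)
    }
    layers[[length(layers) + 1]] <- list(type = "relu")
    if (config$max_pool && L >= 2) {
      layers[[length(layers) + 1]] <- list(type = "pool")
      L <- L %/% 2L
    }
  }
  layers[[length(layers) + 1]] <- list(type = "flatten", L = L, C = C)
  d <- L * C
  for (j in seq_len(config$n_dense)) {
    u <- config$units[j]
    layers[[length(layers) + 1]] <- list(
      type = "dense", act = "relu", l2 = 4e-4,
      W = matrix(stats::rnorm(d * u, sd = sqrt(2 / d)), d, u), b = numeric(u))
    d <- u
  }
  layers[[length(layers) + 1]] <- list(
    type = "dense", act = "linear", l2 = 4e-4,
    W = matrix(stats::rnorm(d, sd = sqrt(1 / d)), d, 1), b = numeric(1))
  layers
}

#' Trainable-parameter count of a CNN configuration
#'
#' Closed-form count of the weights and biases (and batch-norm scale/shift
#' parameters) a configuration instantiates on a given input length.
#'
#' @param config a [cnn_config()].
#' @param n_features input spectrum length.
#' @return integer parameter count.
#' @export
cnn_param_count <- function(config, n_features) {
  total <- 0L; L <- n_features; C <- 1L
  for (i in seq_len(config$n_conv)) {
    k <- config$kernel; f <- config$filters[i]
    total <- total + k * C * f + f
    L <- L - k + 1L; C <- f
    if (config$batch_norm) total <- total + 2L * f
    if (config$max_pool && L >= 2) L <- L %/% 2L
  }
  d <- L * C
  for (j in seq_len(config$n_dense)) {
    total <- total + d * config$units[j] + config$units[j]
    d <- config$units[j]
  }
  as.integer(total + d + 1L)
}

# --- forward / backward --------------------------------------------------
#
# Activations are kept in a (B*L) x C matrix layout throughout (row index
# (t-1)*B + b for batch row b at spatial position t). In this layout the
# im2col blocks of a valid 1-D convolution are contiguous row slices, a
# flatten to the dense stack is a free dim change, and no 3-D reshapes are
# needed anywhere — which is what makes the training loop fast in plain R.

cnn_forward <- function(layers, X, training = FALSE) {
  # X: B x p matrix; returns list(out, cache, layers) — layers returned
  # because batch-norm running statistics are updated in training mode
  B <- nrow(X)
  M <- X
  dim(M) <- c(length(M), 1L)
  cache <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      L <- nrow(M) / B
      Lout <- L - ly$k + 1L
      nr <- B * Lout
      Y <- matrix(rep(ly$b, each = nr), nr, ly$C_out)
      for (o in seq_len(ly$k)) {
        rows <- ((o - 1) * B + 1):((o - 1) * B + nr)
        wrows <- ((o - 1) * ly$C_in + 1):(o * ly$C_in)
        Y <- Y + M[rows, , drop = FALSE] %*% ly$W[wrows, , drop = FALSE]
      }
      cache[[i]] <- list(M = M, L_in = L, B = B)
      M <- Y
    } else if (ly$type == "bn") {
      m <- nrow(M)
      if (training) {
        mu <- colMeans(M)
        v <- colMeans(M * M) - mu^2
        layers[[i]]$rmean <- ly$momentum * ly$rmean + (1 - ly$momentum) * mu
        layers[[i]]$rvar <- ly$momentum * ly$rvar + (1 - ly$momentum) * v
      } else {
        mu <- ly$rmean; v <- ly$rvar
      }
      inv <- 1 / sqrt(v + ly$eps)
      xhat <- (M - rep(mu, each = m)) * rep(inv, each = m)
      M <- xhat * rep(ly$gamma, each = m) + rep(ly$beta, each = m)
      cache[[i]] <- list(xhat = xhat, inv = inv, m = m)
    } else if (ly$type == "relu") {
      mask <- M > 0
      cache[[i]] <- list(mask = mask)
      M <- M * mask
    } else if (ly$type == "pool") {
      L <- nrow(M) / B
      Lout <- L %/% 2L
      idx1 <- rep(seq.int(0L, Lout - 1L) * 2L * B, each = B) + seq_len(B)
      idx2 <- idx1 + B
      M1 <- M[idx1, , drop = FALSE]
      M2 <- M[idx2, , drop = FALSE]
      take1 <- M1 >= M2
      cache[[i]] <- list(take1 = take1, idx1 = idx1, idx2 = idx2, L_in = L, B = B)
      M <- pmax(M1, M2)
    } else if (ly$type == "flatten") {
      cache[[i]] <- list(dims = dim(M))
      dim(M) <- c(B, length(M) / B)
    } else if (ly$type == "dense") {
      cache[[i]] <- list(X = M)
      M <- M %*% ly$W + rep(ly$b, each = B)
      if (ly$act == "relu") {
        mask <- M > 0
        cache[[i]]$mask <- mask
        M <- M * mask
      }
    }
  }
  list(out = as.vector(M), cache = cache, layers = layers)
}

cnn_backward <- function(layers, cache, dout) {
  grads <- vector("list", length(layers))
  G <- dout  # starts as B x 1 matrix
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]; ca <- cache[[i]]
    if (ly$type == "dense") {
      if (ly$act == "relu") G <- G * ca$mask
      grads[[i]] <- list(W = crossprod(ca$X, G), b = colSums(G))
      G <- tcrossprod(G, ly$W)
    } else if (ly$type == "flatten") {
      dim(G) <- ca$dims
    } else if (ly$type == "pool") {
      dM <- matrix(0, ca$L_in * ca$B, ncol(G))
      dM[ca$idx1, ] <- G * ca$take1
      dM[ca$idx2, ] <- G * !ca$take1
      G <- dM
    } else if (ly$type == "relu") {
      G <- G * ca$mask
    } else if (ly$type == "bn") {
      m <- ca$m
      dgamma <- colSums(G * ca$xhat)
      dbeta <- colSums(G)
      dxhat <- G * rep(ly$gamma, each = m)
      dM <- (dxhat - rep(colMeans(dxhat), each = m) -
               ca$xhat * rep(colMeans(dxhat * ca$xhat), each = m)) *
        rep(ca$inv, each = m)
      grads[[i]] <- list(gamma = dgamma, beta = dbeta)
      G <- dM
    } else if (ly$type == "conv") {
      B <- ca$B
      nr <- nrow(G)
      dW <- matrix(0, ly$k * ly$C_in, ly$C_out)
      dM <- matrix(0, ca$L_in * B, ly$C_in)
      for (o in seq_len(ly$k)) {
        rows <- ((o - 1) * B + 1):((o - 1) * B + nr)
        wrows <- ((o - 1) * ly$C_in + 1):(o * ly$C_in)
        dW[wrows, ] <- crossprod(ca$M[rows, , drop = FALSE], G)
        dM[rows, ] <- dM[rows, , drop = FALSE] +
          tcrossprod(G, ly$W[wrows, , drop = FALSE])
      }
      grads[[i]] <- list(W = dW, b = colSums(G))
      G <- dM
    }
  }
  grads
}

# --- Adam ----------------------------------------------------------------
#
# The parameter, moment and gradient vectors are owned exclusively by the
# training loop, so the update runs in place through a small C kernel (one
# fused pass, L2 weight decay folded into the gradient). Weight snapshots
# for early stopping are deep-copied before any further update touches them.

adam_init <- function(layers) {
  lapply(layers, function(ly) {
    if (ly$type %in% c("conv", "dense")) {
      list(mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0)
    } else if (ly$type == "bn") {
      list(mg = ly$gamma * 0, vg = ly$gamma * 0, mb = ly$beta * 0, vb = ly$beta * 0)
    } else NULL
  })
}

adam_step_inplace <- function(layers, grads, state, lr, t, beta1 = 0.9,
                              beta2 = 0.999, eps = 1e-8) {
  bc2s <- sqrt(1 - beta2^t)
  alpha <- lr * bc2s / (1 - beta1^t)
  epsp <- eps * bc2s
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    ly <- layers[[i]]; st <- state[[i]]
    if (ly$type %in% c("conv", "dense")) {
      wd <- if (ly$type == "dense") 2 * ly$l2 else 0
      .Call(C_adam_update, ly$W, g$W, st$mW, st$vW, alpha, beta1, beta2, epsp, wd)
      .Call(C_adam_update, ly$b, g$b, st$mb, st$vb, alpha, beta1, beta2, epsp, 0)
    } else if (ly$type == "bn") {
      .Call(C_adam_update, ly$gamma, g$gamma, st$mg, st$vg, alpha, beta1, beta2, epsp, 0)
      .Call(C_adam_update, ly$beta, g$beta, st$mb, st$vb, alpha, beta1, beta2, epsp, 0)
    }
  }
  invisible(NULL)
}

# deep copy of the trainable state (weights are mutated in place)
copy_layers <- function(layers) {
  lapply(layers, function(ly) {
    for (f in intersect(names(ly), c("W", "b", "gamma", "beta", "rmean", "rvar")))
      ly[[f]] <- ly[[f]] + 0
    ly
  })
}

# --- input / target standardization --------------------------------------

cnn_input_stats <- function(X, standardize) {
  switch(standardize,
    none = NULL,
    minmax = {
      lo <- apply(X, 2, min); hi <- apply(X, 2, max)
      rng <- hi - lo; rng[rng < .Machine$double.eps] <- 1
      list(kind = "minmax", lo = lo, rng = rng)
    },
    zscore = {
      mu <- colMeans(X); s <- apply(X, 2, stats::sd)
      s[s < .Machine$double.eps] <- 1
      list(kind = "zscore", mu = mu, s = s)
    })
}

cnn_apply_stats <- function(X, stats) {
  if (is.null(stats)) return(X)
  if (stats$kind == "minmax") {
    sweep(sweep(X, 2, stats$lo), 2, stats$rng / 2, "/") - 1  # to [-1, 1]
  } else {
    sweep(sweep(X, 2, stats$mu), 2, stats$s, "/")
  }
}

cnn_eval_loss <- function(layers, Xarr, y_std) {
  pred <- cnn_forward(layers, Xarr, training = FALSE)$out
  mean((pred - y_std)^2)
}

# --- training ------------------------------------------------------------

#' Train a 1-D CNN on spectra
#'
#' Full training loop: seeded initialization, Adam with step-decay
#' learning rate (halved every 60 epochs), early stopping on validation
#' loss with patience 40 and best-weight restore, at most `max_epochs`
#' epochs. If no validation set is supplied, a fraction `val_frac` of the
#' training rows is carved out (seeded) to drive early stopping. The
#' response is centered and scaled internally for optimizer conditioning
#' and mapped back at prediction time.
#'
#' @param config a [cnn_config()].
#' @param X,y training spectra matrix and Brix vector.
#' @param seed integer seed governing all training randomness.
#' @param X_val,y_val optional explicit validation set (original units).
#' @param max_epochs training-epoch budget (the Hyperband resource).
#' @param patience early-stopping patience in epochs.
#' @param val_frac validation fraction when no explicit set is given.
#' @return a fitted CNN object (used by [grape_model()] with
#'   `family = "CNN"`); contains the best layers, input/target statistics,
#'   per-epoch loss history and the best epoch.
#' @export
cnn_train <- function(config, X, y, seed = 1L, X_val = NULL, y_val = NULL,
                      max_epochs = 200, patience = 40, val_frac = 0.15) {
  X <- as.matrix(X)
  with_seed(seed, {
    if (is.null(X_val)) {
      n_val <- max(2L, round(val_frac * nrow(X)))
      idx <- sample(nrow(X), n_val)
      X_val <- X[idx, , drop = FALSE]; y_val <- y[idx]
      X <- X[-idx, , drop = FALSE]; y <- y[-idx]
    }
    in_stats <- cnn_input_stats(X, config$standardize)
    y_mu <- mean(y); y_sd <- stats::sd(y)
    if (!is.finite(y_sd) || y_sd < .Machine$double.eps) y_sd <- 1
    Xtr <- cnn_apply_stats(X, in_stats)
    Xva <- cnn_apply_stats(X_val, in_stats)
    ytr <- (y - y_mu) / y_sd
    yva <- (y_val - y_mu) / y_sd
    n <- nrow(Xtr); p <- ncol(Xtr)
    Xva_arr <- array(Xva, c(nrow(Xva), p, 1))
    layers <- cnn_build_layers(config, p)
    state <- adam_init(layers)
    best <- list(loss = Inf, layers = layers, epoch = 0L)
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_loss = numeric(0))
    t_step <- 0; wait <- 0L
    for (epoch in seq_len(max_epochs)) {
      lr <- config$lr * 0.5^((epoch - 1) %/% 60)
      ord <- sample(n)
      starts <- seq(1, n, by = config$batch_size)
      ep_loss <- 0
      for (s in starts) {
        rows <- ord[s:min(s + config$batch_size - 1, n)]
        B <- length(rows)
        Xb <- array(Xtr[rows, , drop = FALSE], c(B, p, 1))
        fw <- cnn_forward(layers, Xb, training = TRUE)
        layers <- fw$layers  # running BN stats
        resid <- fw$out - ytr[rows]
        ep_loss <- ep_loss + sum(resid^2)
        dout <- matrix(2 * resid / B, B, 1)
        grads <- cnn_backward(layers, fw$cache, dout)
        t_step <- t_step + 1
        adam_step_inplace(layers, grads, state, lr, t_step)
      }
      val_loss <- cnn_eval_loss(layers, Xva_arr, yva)
      history[nrow(history) + 1, ] <- list(epoch, ep_loss / n, val_loss)
      if (val_loss < best$loss - 1e-12) {
        best <- list(loss = val_loss, layers = copy_layers(layers), epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
    structure(list(layers = best$layers, config = config, in_stats = in_stats,
                   y_mu = y_mu, y_sd = y_sd, n_features = p,
                   best_epoch = best$epoch,
                   val_rmse = sqrt(best$loss) * y_sd,
                   history = history, seed = as.integer(seed)),
              class = "cnn_fit")
  })
}

#' Predict from a trained CNN
#' @param fit a `cnn_fit` from [cnn_train()].
#' @param X spectra matrix.
#' @param chunk rows per forward pass (bounds memory).
#' @return predicted Brix vector.
#' @export
cnn_predict <- function(fit, X, chunk = 256L) {
  X <- as.matrix(X)
  Xs <- cnn_apply_stats(X, fit$in_stats)
  out <- numeric(nrow(X))
  for (s in seq(1, nrow(X), by = chunk)) {
    rows <- s:min(s + chunk - 1, nrow(X))
    Xb <- array(Xs[rows, , drop = FALSE], c(length(rows), ncol(Xs), 1))
    out[rows] <- cnn_forward(fit$layers, Xb, training = FALSE)$out
  }
  out * fit$y_sd + fit$y_mu
}
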