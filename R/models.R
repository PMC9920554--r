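#' Hyperparameter grids for the grid-searched model families
#'
#' Returns the exact Cartesian search grid used for each family:
#' \describe{
#'   \item{PLS}{number of latent variables 1..100 (capped at
#'     `min(n_features, n_train - 1)` at fit time); 100 configurations.}
#'   \item{RF}{number of trees \{50, 100, 150, 200\} x max-features
#'     \{"max", "sqrt", "log2"\} ("max" = all features); 12 configurations.}
#'   \item{SVR}{RBF kernel; epsilon \{0.01, 0.025, 0.05, 0.075, 0.10,
#'     0.15, 0.20\} x cost \eqn{C \in \{2^{-2}, 2^{-1}, \dots, 2^9\}};
#'     84 configurations.}
#' }
#' Enumeration order is deterministic: columns sorted by parameter name,
#' rows enumerated with the first column varying fastest.
#'
#' @param family `"PLS"`, `"RF"` or `"SVR"` (the CNN is tuned by
#'   [hyperband_cnn()], not a grid).
#' @return a data frame, one row per hyperparameter configuration.
#' @export
#' @examples
#' nrow(grid_for("PLS"))  # 100
#' nrow(grid_for("RF"))   # 12
#' nrow(grid_for("SVR"))  # 84
grid_for <- function(family) {
  switch(family,
    PLS = data.frame(ncomp = 1:100),
    RF = expand.grid(max_features = c("log2", "max", "sqrt"),
                     ntree = c(50, 100, 150, 200),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE),
    SVR = expand.grid(cost = 2^(-2:9),
                      epsilon = c(0.01, 0.025, 0.05, 0.075, 0.10, 0.15, 0.20),
                      KEEP.OUT.ATTRS = FALSE),
    stop("unknown model family: ", family)
  )
}

model_families <- function() c("PLS", "RF", "SVR", "CNN")

rf_mtry <- function(max_features, p) {
  switch(as.character(max_features),
    max = p,
    sqrt = max(1L, floor(sqrt(p))),
    log2 = max(1L, floor(log2(p))),
    stop("unknown max_features: ", max_features)
  )
}

#' Fit one of the four regression families
#'
#' One fit/predict contract over the four learning algorithms of the
#' workflow: partial least squares (PLS), random forest (RF), support
#' vector regression with radial kernel (SVR), and a one-dimensional
#' convolutional neural network (CNN). Features are standardized
#' internally (training statistics only) for PLS and SVR, so the cost grid
#' is comparable across pre-treatments; the CNN applies the per-band input
#' standardization named in its configuration. Refitting with identical
#' data, hyperparameters and seed reproduces predictions exactly.
#'
#' @param family `"PLS"`, `"RF"`, `"SVR"` or `"CNN"`.
#' @param X numeric matrix of spectra (rows = samples).
#' @param y numeric Brix vector.
#' @param hyper named list of hyperparameters: one row of
#'   [grid_for()] for PLS/RF/SVR (e.g. `list(ncomp = 10)`,
#'   `list(ntree = 100, max_features = "sqrt")`,
#'   `list(cost = 8, epsilon = 0.05)`), or a [cnn_config()] for the CNN.
#' @param seed integer seed controlling all training randomness.
#' @param ... further arguments passed to the CNN trainer
#'   (e.g. `X_val`, `y_val`, `max_epochs`).
#' @return an object of class `grape_model` (and a family subclass) with
#'   `predict`, `print` methods. The element `hyper` records the
#'   hyperparameters actually used (e.g. a capped PLS latent-variable
#'   count is recorded in `hyper$ncomp_used`).
#' @export
#' @examples
#' X <- matrix(rnorm(200), 20, 10)
#' y <- X[, 1] * 2 + rnorm(20, sd = 0.1)
#' m <- grape_model("PLS", X, y, list(ncomp = 2), seed = 1)
#' predict(m, X)[1:3]
grape_model <- function(family, X, y, hyper = list(), seed = 1L, ...) {
  X <- as.matrix(X)
  check_that(nrow(X) == length(y), "X rows (%d) != y length (%d)", nrow(X), length(y))
  check_that(nrow(X) >= 2, "need at least 2 training samples")
  check_that(!anyNA(X) && !anyNA(y), "missing values in training data")
  constant_y <- stats::sd(y) < .Machine$double.eps
  if (constant_y) warning("constant response: model fitted but degenerate")
  fit <- switch(family,
    PLS = {
      ncomp <- hyper$ncomp %||% 10
      f <- pls1_fit(X, y, ncomp)
      hyper$ncomp_used <- f$ncomp
      f
    },
    RF = {
      ntree <- hyper$ntree %||% 100
      mtry <- rf_mtry(hyper$max_features %||% "max", ncol(X))
      hyper$mtry <- mtry
      with_seed(seed, randomForest::randomForest(x = X, y = y, ntree = ntree,
                                                 mtry = mtry, importance = FALSE))
    },
    SVR = {
      x_mean <- colMeans(X)
      x_sd <- apply(X, 2, stats::sd)
      x_sd[x_sd < .Machine$double.eps] <- 1
      Xs <- sweep(sweep(X, 2, x_mean), 2, x_sd, "/")
      # gamma: the "scale"/median-style default 1/p on standardized inputs
      hyper$gamma <- hyper$gamma %||% (1 / ncol(X))
      m <- e1071::svm(x = Xs, y = y, type = "eps-regression", kernel = "radial",
                      cost = hyper$cost %||% 1,
                      epsilon = hyper$epsilon %||% 0.1,
                      gamma = hyper$gamma, scale = FALSE)
      list(model = m, x_mean = x_mean, x_sd = x_sd)
    },
    CNN = {
      config <- if (inherits(hyper, "cnn_config")) hyper else do.call(cnn_config, hyper)
      hyper <- config
      cnn_train(config, X, y, seed = seed, ...)
    },
    stop("unknown model family: ", family)
  )
  structure(
    list(family = family, hyper = hyper, fit = fit, seed = as.integer(seed),
         n_features = ncol(X), constant_y = constant_y),
    class = c(paste0("grape_model_", tolower(family)), "grape_model")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict Brix from a fitted model
#'
#' @param object a `grape_model`.
#' @param newdata numeric spectra matrix with the training band layout.
#' @param ... unused.
#' @return numeric vector of predicted Brix.
#' @export
predict.grape_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  check_that(ncol(newdata) == object$n_features,
             "newdata has %d features; model expects %d",
             ncol(newdata), object$n_features)
  switch(object$family,
    PLS = pls1_predict(object$fit, newdata),
    RF = unname(stats::predict(object$fit, newdata)),
    SVR = {
      Xs <- sweep(sweep(newdata, 2, object$fit$x_mean), 2, object$fit$x_sd, "/")
      unname(stats::predict(object$fit$model, Xs))
    },
    CNN = cnn_predict(object$fit, newdata)
  )
}

#' @export
print.grape_model <- function(x, ...) {
  hy <- x$hyper
  if (inherits(hy, "cnn_config")) {
    cat(sprintf("grape_model: CNN (%d conv / %d dense), %d input bands\n",
                hy$n_conv, hy$n_dense, x$n_features))
  } else {
    kv <- paste(names(hy), vapply(hy, function(v) paste(format(v), collapse = ","), ""),
                sep = "=", collapse = ", ")
    cat(sprintf("grape_model: %s (%s), %d input bands\n", x$family, kv, x$n_features))
  }
  invisible(x)
}
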