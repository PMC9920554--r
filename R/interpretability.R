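# Wavelength-importance profiles: pre-hoc mutual information screening and
# post-hoc model-specific importance (PLS VIP, random-forest impurity,
# permutation-sampling SAGE), plus cross-fold mean ranking.

importance_profile <- function(method, wavelengths, score, stderr = NA_real_,
                               fold = NA, family = NA_character_) {
  out <- data.frame(wavelength = wavelengths, score = score, stderr = stderr)
  attr(out, "method") <- method
  attr(out, "fold") <- fold
  attr(out, "family") <- family
  class(out) <- c("importance_profile", "data.frame")
  out
}

#' @export
print.importance_profile <- function(x, ...) {
  cat(sprintf("Importance profile: %s (%d bands, fold %s)\n",
              attr(x, "method"), nrow(x), as.character(attr(x, "fold"))))
  top <- x[order(-x$score), ][1:min(5, nrow(x)), ]
  cat("  top bands (nm):", paste(sprintf("%g (%.3g)", top$wavelength, top$score),
                                 collapse = ", "), "\n")
  invisible(x)
}

# internal: Kraskov k-nearest-neighbour mutual information between two
# continuous scalars (estimator "KSG1"), in nats
ksg_mi <- function(x, y, k = 3L) {
  n <- length(x)
  nx <- integer(n); ny <- integer(n)
  for (i in seq_len(n)) {
    dx <- abs(x - x[i]); dy <- abs(y - y[i])
    dz <- pmax(dx, dy)
    eps <- sort(dz, partial = k + 1)[k + 1]  # k-th neighbour excluding self
    nx[i] <- sum(dx < eps) - 1L
    ny[i] <- sum(dy < eps) - 1L
  }
  digamma(k) + digamma(n) - mean(digamma(nx + 1) + digamma(ny + 1))
}

#' Pre-hoc mutual-information wavelength screening
#'
#' Estimates the mutual information between each band's reflectance and
#' the sugar content with the Kraskov k-nearest-neighbour estimator
#' (k = 3), before any model is fitted. A small seeded jitter
#' (1e-10 of each variable's scale) breaks the ties the estimator's
#' continuity assumption forbids. Estimates are clamped at zero;
#' constant bands score 0 and are flagged.
#'
#' @param X spectra matrix (samples x bands).
#' @param y Brix vector.
#' @param wavelengths band centers (defaults to `X` column names).
#' @param seed seed for the tie-breaking jitter.
#' @param k neighbour count of the estimator.
#' @return an `importance_profile` (method `"MI"`, nats); constant bands
#'   are listed in attribute `"constant_bands"`.
#' @export
mutual_information_profile <- function(X, y, wavelengths = NULL, seed = 1L, k = 3L) {
  X <- as.matrix(X)
  if (is.null(wavelengths)) {
    wavelengths <- suppressWarnings(as.numeric(colnames(X)))
    if (length(wavelengths) != ncol(X) || anyNA(wavelengths))
      wavelengths <- seq_len(ncol(X))
  }
  const <- apply(X, 2, function(col) stats::sd(col) < .Machine$double.eps)
  scores <- with_seed(seed, {
    yj <- y + stats::rnorm(length(y), sd = 1e-10 * max(stats::sd(y), 1e-12))
    vapply(seq_len(ncol(X)), function(j) {
      if (const[j]) return(0)
      xj <- X[, j]
      xj <- xj + stats::rnorm(length(xj), sd = 1e-10 * stats::sd(xj))
      max(0, ksg_mi(xj, yj, k = k))
    }, numeric(1))
  })
  out <- importance_profile("MI", wavelengths, scores)
  attr(out, "constant_bands") <- which(const)
  out
}

#' VIP scores of a fitted PLS model
#'
#' Variable influence on projection over the retained latent variables:
#' \deqn{VIP_j = \sqrt{p \sum_h SSY_h w_{jh}^2 / \sum_h SSY_h}}
#' with \eqn{SSY_h = q_h^2 t_h^\top t_h} the response variance explained
#' by component h and \eqn{w_h} the (unit-norm) weight vectors. The mean
#' of the squared VIP scores equals 1 by construction.
#'
#' @param model a `grape_model` with `family = "PLS"`.
#' @param wavelengths band centers for labelling.
#' @return an `importance_profile` (method `"VIP"`).
#' @export
vip_scores <- function(model, wavelengths = NULL) {
  check_that(inherits(model, "grape_model") && model$family == "PLS",
             "VIP scores require a fitted PLS model")
  f <- model$fit
  p <- nrow(f$W)
  ssy <- f$q^2 * colSums(f$T^2)
  if (sum(ssy) < .Machine$double.eps) {
    vip <- rep(1, p)  # degenerate fit: uniform profile keeps mean(VIP^2)=1
  } else {
    vip <- sqrt(p * drop(f$W^2 %*% ssy) / sum(ssy))
  }
  if (is.null(wavelengths)) wavelengths <- seq_len(p)
  importance_profile("VIP", wavelengths, vip, family = "PLS")
}

#' Impurity (Gini-style) importance of a fitted random forest
#'
#' Normalized total reduction in node impurity (residual sum of squares
#' for regression trees) attributable to each band across the ensemble;
#' scores are non-negative and sum to 1. A band never split on scores 0.
#'
#' @param model a `grape_model` with `family = "RF"`.
#' @param wavelengths band centers for labelling.
#' @return an `importance_profile` (method `"GINI"`).
#' @export
gini_importance <- function(model, wavelengths = NULL) {
  check_that(inherits(model, "grape_model") && model$family == "RF",
             "impurity importance requires a fitted random-forest model")
  imp <- randomForest::importance(model$fit, type = 2)[, 1]
  tot <- sum(imp)
  score <- if (tot > 0) imp / tot else rep(0, length(imp))
  if (is.null(wavelengths)) wavelengths <- seq_along(score)
  importance_profile("GINI", wavelengths, unname(score), family = "RF")
}

#' SAGE: Shapley additive global importance
#'
#' Model-agnostic global feature importance: each band's Shapley-fair
#' contribution to the reduction in expected predictive loss, estimated by
#' sampled feature permutations with held-out features marginalized by
#' background imputation. For each permutation, features are revealed one
#' at a time in permuted order and the loss drop attributed to the feature
#' just revealed; the telescoping construction makes the scores sum to
#' loss(nothing revealed) - loss(everything revealed) per permutation
#' (the efficiency property). Monte-Carlo standard errors across
#' permutations are returned as a convergence diagnostic.
#'
#' @param model a `grape_model` (any family), or a function
#'   `function(X) predictions`.
#' @param X_bg background matrix used to impute hidden features (a
#'   training-fold sample; at most `max_background` rows are used).
#' @param X_eval,y_eval evaluation spectra and observed Brix.
#' @param n_permutations number of sampled permutations (>= 1).
#' @param seed integer seed.
#' @param wavelengths band centers for labelling.
#' @param max_background cap on background rows.
#' @return an `importance_profile` (method `"SAGE"`) with per-band scores
#'   and Monte-Carlo standard errors; attributes `"baseline_loss"` and
#'   `"full_loss"` carry the efficiency end points.
#' @export
sage_values <- function(model, X_bg, X_eval, y_eval, n_permutations = 256L,
                        seed = 1L, wavelengths = NULL, max_background = 128L) {
  predict_fun <- if (is.function(model)) model else function(X) predict(model, X)
  X_bg <- as.matrix(X_bg); X_eval <- as.matrix(X_eval)
  check_that(n_permutations >= 1, "n_permutations must be >= 1")
  p <- ncol(X_eval); n_eval <- nrow(X_eval)
  loss <- function(pred) (pred - y_eval)^2   # per-row squared error
  with_seed(seed, {
    if (nrow(X_bg) > max_background)
      X_bg <- X_bg[sample(nrow(X_bg), max_background), , drop = FALSE]
    phi <- matrix(0, n_permutations, p)
    base_losses <- full_losses <- numeric(n_permutations)
    for (t in seq_len(n_permutations)) {
      perm <- sample(p)
      bg_rows <- sample(nrow(X_bg), n_eval, replace = TRUE)
      Xm <- X_bg[bg_rows, , drop = FALSE]  # nothing revealed yet
      prev <- mean(loss(predict_fun(Xm)))
      base_losses[t] <- prev
      for (j in perm) {
        Xm[, j] <- X_eval[, j]
        cur <- mean(loss(predict_fun(Xm)))
        phi[t, j] <- prev - cur
        prev <- cur
      }
      full_losses[t] <- prev
    }
    score <- colMeans(phi)
    se <- apply(phi, 2, stats::sd) / sqrt(n_permutations)
    if (n_permutations == 1) se <- rep(NA_real_, p)
    if (is.null(wavelengths)) wavelengths <- seq_len(p)
    out <- importance_profile("SAGE", wavelengths, score, stderr = se)
    attr(out, "baseline_loss") <- mean(base_losses)
    attr(out, "full_loss") <- mean(full_losses)
    out
  })
}

#' Cross-fold mean importance
#'
#' Averages per-fold importance profiles elementwise, and also averages
#' the per-fold rank of each band (rank 1 = most important), mirroring the
#' mean feature ranking used to stabilize per-fold profiles.
#'
#' @param profiles a list (>= 2) of `importance_profile` objects sharing
#'   one method and wavelength grid.
#' @return an `importance_profile` with fold `"mean"`; column
#'   `mean_rank` carries the averaged per-fold ranks.
#' @export
mean_rank <- function(profiles) {
  check_that(length(profiles) >= 2, "need at least 2 fold profiles")
  methods <- unique(vapply(profiles, attr, "", "method"))
  check_that(length(methods) == 1, "profiles mix methods: %s",
             paste(methods, collapse = ", "))
  wl <- profiles[[1]]$wavelength
  for (pr in profiles)
    check_that(identical(pr$wavelength, wl), "mismatched wavelength grids")
  S <- vapply(profiles, `[[`, numeric(length(wl)), "score")
  rk <- apply(-S, 2, rank, ties.method = "average")
  out <- importance_profile(methods, wl, rowMeans(S), fold = "mean")
  out$mean_rank <- rowMeans(rk)
  out
}
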