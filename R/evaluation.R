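#' Random k-fold assignment
#'
#' Seeded uniform shuffle partitioned into k near-equal folds (sizes
#' differ by at most one). Optional stratification orders samples by the
#' response within quantile bins before dealing them round-robin, which
#' balances the response distribution across folds; it is off by default.
#'
#' @param n number of samples.
#' @param k number of folds (2 <= k <= n).
#' @param seed integer seed.
#' @param stratify_y optional numeric response to stratify on.
#' @return integer vector of fold indices in 1..k, one per sample.
#' @export
#' @examples
#' table(make_folds(11, 5, seed = 1))  # sizes 3,2,2,2,2 in some order
make_folds <- function(n, k, seed = 1L, stratify_y = NULL) {
  check_that(n >= k, "n (%d) must be >= k (%d)", n, k)
  check_that(k >= 2, "need at least 2 folds")
  with_seed(seed, {
    if (is.null(stratify_y)) {
      sizes <- rep(n %/% k, k) + c(rep(1, n %% k), rep(0, k - n %% k))
      folds <- integer(n)
      folds[sample(n)] <- rep(seq_len(k), times = sizes)
      folds
    } else {
      ord <- order(stratify_y, stats::runif(n))  # ties broken at random
      folds <- integer(n)
      folds[ord] <- rep_len(sample(k), n)
      folds
    }
  })
}

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - \sum_i (y_i - \hat y_i)^2 / \sum_i (y_i - \bar y)^2}.
#'
#' @param y observed values (non-constant).
#' @param yhat predicted values.
#' @return scalar R-squared.
#' @export
#' @examples
#' r_squared(c(1, 2, 3, 4), c(1, 2, 3, 5))  # 0.8
r_squared <- function(y, yhat) {
  check_that(length(y) == length(yhat) && length(y) >= 2, "need equal lengths >= 2")
  ss_tot <- sum((y - mean(y))^2)
  check_that(ss_tot > 0, "R-squared undefined for constant observed values")
  1 - sum((y - yhat)^2) / ss_tot
}

#' Root mean squared error
#'
#' \eqn{\sqrt{\frac{1}{N}\sum_i (y_i - \hat y_i)^2}}, in the units of the
#' response (degrees Brix here).
#'
#' @param y observed values.
#' @param yhat predicted values.
#' @return scalar RMSE.
#' @export
#' @examples
#' rmse(c(1, 2, 3, 4), c(1, 2, 3, 5))  # 0.5
rmse <- function(y, yhat) {
  check_that(length(y) == length(yhat) && length(y) >= 1, "need equal non-empty lengths")
  sqrt(mean((y - yhat)^2))
}

#' Ratio of performance to interquartile range
#'
#' RPIQ = (Q3 - Q1) of the observed values divided by the RMSE of
#' prediction; quartiles use the linear-interpolation convention shared
#' with [summary.spectral_library()]. Unlike RPD it makes no normality
#' assumption about the observed values.
#'
#' @param y observed values (>= 4 recommended).
#' @param yhat predicted values.
#' @return scalar RPIQ.
#' @export
#' @examples
#' rpiq(c(1, 2, 3, 4), c(1, 2, 3, 5))  # 3
rpiq <- function(y, yhat) {
  e <- rmse(y, yhat)
  check_that(e > 0, "undefined RPIQ (perfect fit)")
  q <- quartiles(y)
  (q[3] - q[1]) / e
}

fold_metric_row <- function(fold, y, yhat) {
  data.frame(fold = fold, n_test = length(y),
             r2 = r_squared(y, yhat), rmse = rmse(y, yhat),
             rpiq = rpiq(y, yhat))
}

#' Nested 5-fold cross-validation of one (pre-treatment, family) cell
#'
#' The outer loop holds out each fold as an independent test set. Inside
#' each calibration set, hyperparameters are selected by the family's
#' internal procedure — a full internal 5-fold cross-validation scoring
#' every grid point for PLS/RF/SVR, or a Hyperband search with a fixed
#' internal validation split for the CNN — using mean internal-validation
#' RMSE as the sole selection criterion. The selected configuration is
#' refit on the full calibration set and evaluated on the held-out fold
#' with R-squared, RMSE and RPIQ (per-fold observed quartiles).
#'
#' The returned report carries the per-fold held-out predictions and the
#' index sets, so every reported number can be recomputed and the absence
#' of train/test leakage audited.
#'
#' @param library a `spectral_library` (>= 10 samples).
#' @param chain pre-treatment chain label applied before modelling (all
#'   nine chains are per-spectrum, so this leaks nothing across folds).
#' @param family `"PLS"`, `"RF"`, `"SVR"` or `"CNN"`.
#' @param seed master seed; fold splitting, fitting and tuning derive
#'   their seeds from it (see [derive_seed()]).
#' @param k_outer,k_inner outer/inner fold counts.
#' @param hyperband settings list for the CNN search: `n_configs`,
#'   `max_resource`, `eta`, `val_frac` (see [hyperband_cnn()]).
#' @param grid optional replacement hyperparameter grid (a data frame as
#'   from [grid_for()]); defaults to the family's full grid.
#' @return an object of class `cv_report`: per-fold metrics, chosen
#'   hyperparameters, internal-validation RMSEs, held-out predictions,
#'   fold index sets, and fold-mean metrics.
#' @export
nested_cv <- function(library, chain, family, seed = 1L,
                      k_outer = 5L, k_inner = 5L,
                      hyperband = list(n_configs = 8L, max_resource = 200L,
                                       eta = 3, val_frac = 0.2),
                      grid = NULL) {
  stopifnot(inherits(library, "spectral_library"))
  check_that(n_samples(library) >= 10, "nested CV needs at least 10 samples")
  treated <- apply_chain(chain, library)
  X <- treated$spectra
  y <- treated$samples$brix
  n <- nrow(X)
  outer <- make_folds(n, k_outer, derive_seed(seed, "outer-folds"))
  folds <- vector("list", k_outer)
  for (e in seq_len(k_outer)) {
    test_idx <- which(outer == e)
    calib_idx <- which(outer != e)
    Xc <- X[calib_idx, , drop = FALSE]; yc <- y[calib_idx]
    if (family == "CNN") {
      hb <- hyperband_cnn(Xc, yc, seed = derive_seed(seed, "hb", e),
                          n_configs = hyperband$n_configs %||% 8L,
                          max_resource = hyperband$max_resource %||% 200L,
                          eta = hyperband$eta %||% 3,
                          val_frac = hyperband$val_frac %||% 0.2)
      chosen <- hb$best_config
      internal_rmse <- hb$best_val_rmse
      model <- grape_model("CNN", Xc, yc, chosen,
                           seed = derive_seed(seed, "refit", e))
    } else {
      gr <- grid %||% grid_for(family)
      inner <- make_folds(length(calib_idx), k_inner,
                          derive_seed(seed, "inner-folds", e))
      score <- inner_grid_scores(family, gr, Xc, yc, inner, seed, e)
      best_row <- which.min(score)   # ties -> first in enumeration order
      chosen <- as.list(gr[best_row, , drop = FALSE])
      internal_rmse <- score[best_row]
      model <- grape_model(family, Xc, yc, chosen,
                           seed = derive_seed(seed, "refit", e))
    }
    yhat <- predict(model, X[test_idx, , drop = FALSE])
    folds[[e]] <- list(
      metrics = fold_metric_row(e, y[test_idx], yhat),
      hyper = model$hyper, internal_rmse = internal_rmse,
      predictions = data.frame(sample_id = treated$samples$sample_id[test_idx],
                               y_true = y[test_idx], y_pred = yhat),
      test_idx = test_idx, calib_idx = calib_idx)
  }
  metrics <- do.call(rbind, lapply(folds, `[[`, "metrics"))
  structure(
    list(variety = paste(unique(treated$samples$variety), collapse = "+"),
         family = family, chain = if (inherits(chain, "pretreatment_chain")) chain$label else chain,
         folds = folds, metrics = metrics,
         mean_r2 = mean(metrics$r2), mean_rmse = mean(metrics$rmse),
         mean_rpiq = mean(metrics$rpiq),
         mean_internal_rmse = mean(vapply(folds, `[[`, numeric(1), "internal_rmse")),
         seed = as.integer(seed)),
    class = "cv_report")
}

# internal: mean internal-CV RMSE per grid row; PLS uses the all-components
# fast path (one fit per inner fold scores every latent-variable count)
inner_grid_scores <- function(family, gr, Xc, yc, inner, seed, e) {
  k_inner <- max(inner)
  if (family == "PLS") {
    se <- matrix(0, k_inner, nrow(gr))  # summed squared error per fold x ncomp
    nv <- integer(k_inner)
    for (v in seq_len(k_inner)) {
      tr <- inner != v
      f <- pls1_fit(Xc[tr, , drop = FALSE], yc[tr], max(gr$ncomp))
      pred <- pls1_predict_all(f, Xc[!tr, , drop = FALSE])
      ncomp_eff <- pmin(gr$ncomp, f$ncomp)  # cap at what the data support
      se[v, ] <- vapply(seq_len(nrow(gr)), function(j) {
        sum((pred[, ncomp_eff[j]] - yc[!tr])^2)
      }, numeric(1))
      nv[v] <- sum(!tr)
    }
    colMeans(sqrt(sweep(se, 1, nv, "/")))
  } else {
    vapply(seq_len(nrow(gr)), function(j) {
      hy <- as.list(gr[j, , drop = FALSE])
      fold_rmse <- vapply(seq_len(k_inner), function(v) {
        tr <- inner != v
        m <- grape_model(family, Xc[tr, , drop = FALSE], yc[tr], hy,
                         seed = derive_seed(seed, "inner-fit", e, v, j))
        rmse(yc[!tr], predict(m, Xc[!tr, , drop = FALSE]))
      }, numeric(1))
      mean(fold_rmse)
    }, numeric(1))
  }
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Nested CV report: %s | %s | %s\n", x$variety, x$family, x$chain))
  m <- x$metrics
  m[, c("r2", "rmse", "rpiq")] <- round(m[, c("r2", "rmse", "rpiq")], 3)
  print.data.frame(m, row.names = FALSE)
  cat(sprintf("fold means: R2 %.3f | RMSE %.3f | RPIQ %.3f (internal RMSE %.3f)\n",
              x$mean_r2, x$mean_rmse, x$mean_rpiq, x$mean_internal_rmse))
  invisible(x)
}

#' @export
summary.cv_report <- function(object, ...) {
  data.frame(variety = object$variety, family = object$family,
             chain = object$chain, mean_r2 = object$mean_r2,
             mean_rmse = object$mean_rmse, mean_rpiq = object$mean_rpiq,
             mean_internal_rmse = object$mean_internal_rmse)
}

#' Select the best pre-treatment per (variety, family)
#'
#' Selection is keyed on mean internal-validation RMSE — the criterion
#' used during tuning — never on test metrics. Ties are broken by the
#' simpler chain (fewer steps), then lexicographically.
#'
#' @param reports a list of `cv_report` objects.
#' @return a data frame with one row per (variety, family): the selected
#'   chain and its fold-mean metrics, plus a `best` flag in the full table
#'   attached as attribute `"all"`.
#' @export
select_best <- function(reports) {
  tab <- do.call(rbind, lapply(reports, summary))
  tab$n_steps <- vapply(strsplit(tab$chain, "+", fixed = TRUE), length, 0L)
  keys <- split(seq_len(nrow(tab)), paste(tab$variety, tab$family, sep = " / "))
  pick <- vapply(keys, function(idx) {
    o <- idx[order(tab$mean_internal_rmse[idx], tab$n_steps[idx], tab$chain[idx])]
    o[1]
  }, 0L)
  tab$best <- seq_len(nrow(tab)) %in% pick
  out <- tab[pick, setdiff(names(tab), "n_steps"), drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all") <- tab[, setdiff(names(tab), "n_steps")]
  out
}
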