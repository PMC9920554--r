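# Orchestration of the full study design: per variety, every requested
# (model family x spectral input) cell under nested cross-validation,
# best-pre-treatment selection on the internal criterion, then importance
# profiles for the selected models — all from one config, fully seeded.

#' Experiment configuration
#'
#' @param library a `spectral_library`, or `NULL` to generate one from
#'   `generator` at run time.
#' @param generator a [generator_config()] used when `library` is `NULL`.
#' @param varieties varieties to model (each independently); defaults to
#'   those present in the library.
#' @param chains pre-treatment chain labels (default: all nine).
#' @param families model families (default: all four).
#' @param seed master seed; every downstream seed derives from it.
#' @param hyperband CNN search settings (see [nested_cv()]).
#' @param importance compute importance profiles for the selected models
#'   (mutual information is always computed per variety).
#' @param sage_permutations permutation budget for SAGE profiles.
#' @param out_dir output directory for the CSV bundle, or `NULL` to skip
#'   writing.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(library = NULL, generator = generator_config(),
                              varieties = NULL, chains = NULL, families = NULL,
                              seed = 1L,
                              hyperband = list(n_configs = 8L, max_resource = 200L),
                              importance = TRUE, sage_permutations = 32L,
                              out_dir = NULL) {
  chains <- chains %||% names(pretreatment_registry())
  families <- families %||% model_families()
  check_that(all(chains %in% names(pretreatment_registry())),
             "unknown chains: %s",
             paste(setdiff(chains, names(pretreatment_registry())), collapse = ", "))
  check_that(all(families %in% model_families()),
             "unknown families: %s",
             paste(setdiff(families, model_families()), collapse = ", "))
  structure(list(library = library, generator = generator,
                 varieties = varieties, chains = chains, families = families,
                 seed = as.integer(seed), hyperband = hyperband,
                 importance = importance,
                 sage_permutations = as.integer(sage_permutations),
                 out_dir = out_dir),
            class = "experiment_config")
}

#' Run the full modelling experiment
#'
#' For each variety (modelled independently) and each requested model
#' family, runs nested cross-validation over every requested pre-treatment
#' chain, selects the best chain by mean internal-validation RMSE, and
#' (optionally) computes wavelength-importance profiles for the selected
#' models: mutual information per variety (pre-hoc, on reflectance), VIP
#' for PLS, impurity importance for RF, and SAGE for SVR/CNN — each per
#' outer fold, with the cross-fold mean rank attached.
#'
#' A failing (variety, family, chain) cell is recorded with its error
#' message and the run continues. When `out_dir` is set, the bundle is
#' written as plain CSVs (`metrics.csv`, `fold_means.csv`,
#' `predictions.csv`, `importance.csv`, `best.csv`) plus a JSON manifest
#' of seeds and settings.
#'
#' @param config an [experiment_config()].
#' @return an `experiment_bundle`: the library summary, all `cv_report`s,
#'   the selection table, importance profiles, failures, and the manifest.
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  lib <- config$library %||% generate_library(config$generator)
  varieties <- config$varieties %||% unique(lib$samples$variety)
  check_that(all(varieties %in% lib$samples$variety),
             "varieties not in library: %s",
             paste(setdiff(varieties, lib$samples$variety), collapse = ", "))
  reports <- list(); failures <- list()
  for (v in varieties) {
    vlib <- lib[lib$samples$variety == v]
    for (fam in config$families) {
      for (ch in config$chains) {
        key <- paste(v, fam, ch, sep = " / ")
        res <- tryCatch(
          nested_cv(vlib, ch, fam,
                    seed = derive_seed(config$seed, "cv", v, fam, ch),
                    hyperband = config$hyperband),
          error = function(e) e)
        if (inherits(res, "error")) {
          failures[[key]] <- conditionMessage(res)
        } else {
          reports[[key]] <- res
        }
      }
    }
  }
  check_that(length(reports) > 0, "all cells failed; first error: %s",
             if (length(failures)) failures[[1]] else "none")
  best <- select_best(reports)
  importance <- if (config$importance) {
    experiment_importance(lib, varieties, reports, best, config)
  } else NULL
  manifest <- list(
    seed = config$seed, varieties = varieties, chains = config$chains,
    families = config$families, n_samples = n_samples(lib),
    hyperband = config$hyperband,
    package_version = as.character(utils::packageVersion("grapespec")),
    timestamp = format(Sys.time(), tz = "UTC"))
  bundle <- structure(
    list(summary = summary(lib), reports = reports, best = best,
         importance = importance, failures = failures, manifest = manifest),
    class = "experiment_bundle")
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

# internal: importance profiles for the selected (variety, family) models
experiment_importance <- function(lib, varieties, reports, best, config) {
  out <- list()
  for (v in varieties) {
    vlib <- lib[lib$samples$variety == v]
    mi <- mutual_information_profile(vlib$spectra, vlib$samples$brix,
                                     wavelengths = vlib$wavelengths,
                                     seed = derive_seed(config$seed, "mi", v))
    out[[paste(v, "MI", sep = " / ")]] <- mi
    vbest <- best[best$variety == v, , drop = FALSE]
    for (r in seq_len(nrow(vbest))) {
      fam <- vbest$family[r]; ch <- vbest$chain[r]
      rep_key <- paste(v, fam, ch, sep = " / ")
      report <- reports[[rep_key]]
      if (is.null(report)) next
      treated <- apply_chain(ch, vlib)
      profs <- lapply(seq_along(report$folds), function(e) {
        fold <- report$folds[[e]]
        Xc <- treated$spectra[fold$calib_idx, , drop = FALSE]
        yc <- treated$samples$brix[fold$calib_idx]
        Xt <- treated$spectra[fold$test_idx, , drop = FALSE]
        yt <- treated$samples$brix[fold$test_idx]
        seed_e <- derive_seed(config$seed, "imp", v, fam, e)
        model <- grape_model(if (fam == "CNN") "CNN" else fam, Xc, yc,
                             report$folds[[e]]$hyper, seed = seed_e)
        pr <- switch(fam,
          PLS = vip_scores(model, treated$wavelengths),
          RF = gini_importance(model, treated$wavelengths),
          sage_values(model, Xc, Xt, yt,
                      n_permutations = config$sage_permutations,
                      seed = seed_e, wavelengths = treated$wavelengths))
        attr(pr, "fold") <- e
        pr
      })
      mr <- mean_rank(profs)
      attr(mr, "family") <- fam
      key <- paste(v, fam, sep = " / ")
      out[[key]] <- list(folds = profs, mean = mr, chain = ch)
    }
  }
  out
}

# internal: flatten bundle into the CSV layout
bundle_tables <- function(bundle) {
  hyper_string <- function(hy) {
    if (inherits(hy, "cnn_config")) {
      paste0("std=", hy$standardize, ";conv=", paste(hy$filters, collapse = "|"),
             ";kernel=", hy$kernel, ";bn=", hy$batch_norm, ";pool=", hy$max_pool,
             ";dense=", paste(hy$units, collapse = "|"),
             ";batch=", hy$batch_size, ";lr=", signif(hy$lr, 4))
    } else {
      paste(names(hy), vapply(hy, function(x) paste(format(x), collapse = "|"), ""),
            sep = "=", collapse = ";")
    }
  }
  metrics <- do.call(rbind, lapply(names(bundle$reports), function(key) {
    r <- bundle$reports[[key]]
    m <- r$metrics
    m$chosen_hyperparameters <- vapply(r$folds, function(f) hyper_string(f$hyper), "")
    cbind(data.frame(variety = r$variety, model = r$family, pretreatment = r$chain),
          m)
  }))
  predictions <- do.call(rbind, lapply(names(bundle$reports), function(key) {
    r <- bundle$reports[[key]]
    do.call(rbind, lapply(seq_along(r$folds), function(e) {
      cbind(data.frame(variety = r$variety, model = r$family,
                       pretreatment = r$chain, fold = e),
            r$folds[[e]]$predictions)
    }))
  }))
  fold_means <- do.call(rbind, lapply(bundle$reports, summary))
  rownames(fold_means) <- NULL
  importance <- NULL
  if (!is.null(bundle$importance)) {
    rows <- list()
    for (key in names(bundle$importance)) {
      item <- bundle$importance[[key]]
      parts <- strsplit(key, " / ", fixed = TRUE)[[1]]
      if (inherits(item, "importance_profile")) {  # MI: per variety, no folds
        rows[[key]] <- data.frame(method = "MI", variety = parts[1], model = NA,
                                  fold = "all", wavelength_nm = item$wavelength,
                                  score = item$score, mc_stderr = NA)
      } else {
        per_fold <- lapply(item$folds, function(pr) {
          data.frame(method = attr(pr, "method"), variety = parts[1],
                     model = parts[2], fold = as.character(attr(pr, "fold")),
                     wavelength_nm = pr$wavelength, score = pr$score,
                     mc_stderr = pr$stderr)
        })
        mr <- item$mean
        rows[[key]] <- rbind(do.call(rbind, per_fold),
                             data.frame(method = attr(mr, "method"),
                                        variety = parts[1], model = parts[2],
                                        fold = "mean",
                                        wavelength_nm = mr$wavelength,
                                        score = mr$score, mc_stderr = NA))
      }
    }
    importance <- do.call(rbind, rows)
    rownames(importance) <- NULL
  }
  list(metrics = metrics, fold_means = fold_means, predictions = predictions,
       importance = importance)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- bundle_tables(bundle)
  utils::write.csv(tabs$metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  utils::write.csv(tabs$fold_means, file.path(out_dir, "fold_means.csv"), row.names = FALSE)
  utils::write.csv(tabs$predictions, file.path(out_dir, "predictions.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$best), file.path(out_dir, "best.csv"),
                   row.names = FALSE)
  if (!is.null(tabs$importance))
    utils::write.csv(tabs$importance, file.path(out_dir, "importance.csv"),
                     row.names = FALSE)
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Human-readable experiment summary
#'
#' Per variety: the selected (family, pre-treatment) cells with their
#' fold-mean metrics, the single best family flagged (minimum mean
#' internal-validation RMSE), failed cells, and the top mean-ranked
#' wavelengths per importance method.
#'
#' @param bundle an `experiment_bundle` from [run_experiment()].
#' @param top_n how many top wavelengths to list per method.
#' @return a list with elements `selection` (data frame, one row per
#'   (variety, family), `overall_best` flag included), `failures`, and
#'   `top_wavelengths`; printed compactly.
#' @export
report_experiment <- function(bundle, top_n = 10L) {
  stopifnot(inherits(bundle, "experiment_bundle"))
  sel <- as.data.frame(bundle$best)
  flag <- logical(nrow(sel))
  for (v in unique(sel$variety)) {
    rows <- which(sel$variety == v)
    flag[rows[which.min(sel$mean_internal_rmse[rows])]] <- TRUE
  }
  sel$overall_best <- flag
  top <- list()
  if (!is.null(bundle$importance)) {
    for (key in names(bundle$importance)) {
      item <- bundle$importance[[key]]
      pr <- if (inherits(item, "importance_profile")) item else item$mean
      top[[key]] <- pr$wavelength[order(-pr$score)][seq_len(min(top_n, nrow(pr)))]
    }
  }
  out <- list(selection = sel, failures = bundle$failures, top_wavelengths = top)
  class(out) <- "experiment_report"
  out
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Experiment summary (selection by mean internal-validation RMSE)\n")
  sel <- x$selection
  num <- vapply(sel, is.numeric, TRUE)
  sel[num] <- lapply(sel[num], round, 3)
  print.data.frame(sel, row.names = FALSE)
  if (length(x$failures)) {
    cat("failed cells:\n")
    for (k in names(x$failures)) cat(sprintf("  %s: %s\n", k, x$failures[[k]]))
  }
  if (length(x$top_wavelengths)) {
    cat("top mean-ranked wavelengths (nm):\n")
    for (k in names(x$top_wavelengths))
      cat(sprintf("  %s: %s\n", k, paste(x$top_wavelengths[[k]], collapse = ", ")))
  }
  invisible(x)
}

#' @export
print.experiment_bundle <- function(x, ...) {
  cat(sprintf("Experiment bundle: %d cell reports, %d failures\n",
              length(x$reports), length(x$failures)))
  print(report_experiment(x))
  invisible(x)
}
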