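# Shared fixtures, built in code.

# tiny deterministic library on an arbitrary sub-grid
toy_library <- function(n = 6, wavelengths = seq(400, 490, by = 10), seed = 1) {
  withr::with_seed(seed, {
    base <- 0.4 + 0.2 * sin(seq_along(wavelengths) / 3)
    spectra <- t(replicate(n, base + stats::rnorm(length(wavelengths), sd = 0.02)))
    spectra <- pmin(pmax(spectra, 0.05), 1.1)
    spectral_library(spectra, wavelengths,
                     brix = round(stats::runif(n, 8, 28), 1),
                     variety = rep(c("Syrah", "Malagouzia"), length.out = n),
                     year = 2020L, bunch_label = "B01")
  })
}

# library whose Brix is an exact linear map of one band (noise-free signal)
one_band_library <- function(n = 60, p = 20, informative = 7, seed = 3) {
  withr::with_seed(seed, {
    wl <- seq(500, 500 + 10 * (p - 1), by = 10)
    spectra <- matrix(stats::runif(n * p, 0.2, 0.8), n, p)
    brix <- 5 + 25 * (spectra[, informative] - 0.2) / 0.6
    spectral_library(spectra, wl, brix = brix, variety = "Syrah")
  })
}

syrah_library <- local({
  cache <- new.env()
  function(n = 160, seed = 7) {
    key <- paste0("n", n, "s", seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <- generate_library(
        generator_config(n_per_variety = n, varieties = "Syrah", seed = seed))
    }
    cache[[key]]
  }
})

sugar_coupled_centers <- function() {
  pr <- variety_presets()$Syrah
  pr$bands$center[pr$bands$sugar_coupling > 0]
}

# exhaustive Shapley oracle for the SAGE value of a model under marginal
# background imputation: enumerates all 2^p coalitions exactly
exact_sage <- function(predict_fun, X_bg, X_eval, y_eval) {
  p <- ncol(X_eval)
  v <- function(S) {
    # expected loss reduction vs baseline when exactly S is revealed,
    # expectation over all background rows
    tot <- 0
    for (b in seq_len(nrow(X_bg))) {
      Xm <- X_bg[rep(b, nrow(X_eval)), , drop = FALSE]
      Xm[, S] <- X_eval[, S, drop = FALSE]
      tot <- tot + mean((predict_fun(Xm) - y_eval)^2)
    }
    tot / nrow(X_bg)
  }
  subsets <- lapply(0:(2^p - 1), function(m) which(bitwAnd(m, 2^(0:(p - 1))) > 0))
  vals <- vapply(subsets, v, numeric(1))
  key <- vapply(subsets, function(S) sum(2^(S - 1)), numeric(1))
  phi <- numeric(p)
  for (j in seq_len(p)) {
    for (i in seq_along(subsets)) {
      S <- subsets[[i]]
      if (j %in% S) next
      w <- factorial(length(S)) * factorial(p - length(S) - 1) / factorial(p)
      with_j <- vals[match(sum(2^(S - 1)) + 2^(j - 1), key)]
      phi[j] <- phi[j] + w * (vals[i] - with_j)
    }
  }
  phi
}
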