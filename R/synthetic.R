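# Synthetic grape-spectra generator.
#
# Emulates the statistical structure the modelling pipeline assumes:
# smooth reflectance baselines, fixed pigment/water absorption bands near
# 680/970/1200/1440/1920 nm, sugar-coupled band depths concentrated in
# 550-1300 nm, multiplicative/additive scatter, detector-region noise, and
# per-variety Brix distributions with the field-study moments. It carries
# the structure needed to exercise every pipeline stage; it is not a
# radiative-transfer or berry-optics model, and its sugar couplings are
# tunable stand-ins, not estimates of grape chemistry.

default_bands <- function() {
  # center nm | Gaussian sigma nm | Brix-independent depth | depth per Brix
  data.frame(
    center = c(680, 730, 920, 960, 1150, 970, 1200, 1440, 1920),
    width = c(22, 20, 25, 25, 30, 30, 40, 55, 65),
    base_depth = c(0.30, 0.02, 0.03, 0.10, 0.03, 0.12, 0.18, 0.85, 1.15),
    sugar_coupling = c(0.003, 0.003, 0.003, 0.003, 0.003, 0, 0, 0, 0)
  )
}

#' Default variety presets for the synthetic generator
#'
#' One preset per variety, carrying the Brix distribution moments of the
#' field study (mean, standard deviation, minimum, maximum per variety;
#' all Brix values lie in the global 4.2--31.4 range), a smooth baseline
#' albedo, the absorption-band list (fixed water/pigment bands at
#' 680/970/1200/1440/1920 nm plus sugar-coupled bands at
#' 680/730/920/960/1150 nm), scatter magnitudes and per-detector noise
#' levels (three detector regions with increasing noise towards the SWIR).
#' The red variety (Syrah) carries an extra anthocyanin-like absorption
#' that lowers its baseline in the 450--700 nm range.
#'
#' @return named list of `variety_preset` lists.
#' @export
variety_presets <- function() {
  base <- list(
    albedo = c(low = 0.08, high = 0.55, mid = 620, width = 90, swir_drop = 0.35),
    red_pigment = 0,
    bands = default_bands(),
    scatter = c(mult_sd = 0.05, add_sd = 0.01),
    noise_sd = c(vnir = 0.002, nir = 0.004, swir = 0.006)
  )
  preset <- function(name, mean, sd, min, max, red = 0) {
    out <- base
    out$name <- name
    out$brix <- c(mean = mean, sd = sd, min = min, max = max)
    out$red_pigment <- red
    class(out) <- "variety_preset"
    out
  }
  list(
    "Chardonnay" = preset("Chardonnay", 19.73, 3.62, 10.0, 30.0),
    "Malagouzia" = preset("Malagouzia", 18.63, 5.06, 6.8, 30.0),
    "Sauvignon-Blanc" = preset("Sauvignon-Blanc", 17.61, 6.14, 4.2, 31.4),
    "Syrah" = preset("Syrah", 17.22, 5.04, 4.9, 30.0, red = 0.45)
  )
}

#' Draw Brix values from a variety preset
#'
#' Truncated-normal draws: normal with the preset mean and standard
#' deviation, restricted to \[preset min, preset max\] by inverse-CDF
#' sampling (no rejection, fully deterministic under the seed).
#'
#' @param preset a `variety_preset`.
#' @param n number of draws.
#' @param seed integer seed.
#' @return numeric vector of Brix values within the preset window.
#' @export
sample_brix <- function(preset, n, seed = 1L) {
  check_that(n >= 1, "n must be >= 1")
  b <- preset$brix
  check_that(b["min"] <= b["max"], "invalid truncation window")
  if (b["sd"] <= 0) return(rep(unname(b["mean"]), n))
  with_seed(seed, {
    lo <- stats::pnorm(b["min"], b["mean"], b["sd"])
    hi <- stats::pnorm(b["max"], b["mean"], b["sd"])
    u <- stats::runif(n, lo, hi)
    unname(stats::qnorm(u, b["mean"], b["sd"]))
  })
}

# internal: smooth baseline albedo curve on the wavelength grid
baseline_albedo <- function(wavelengths, preset) {
  a <- preset$albedo
  curve <- a["low"] + a["high"] * stats::plogis((wavelengths - a["mid"]) / a["width"])
  curve <- curve * (1 - a["swir_drop"] * pmax(0, wavelengths - 1300) / 1200)
  if (preset$red_pigment > 0) {
    curve <- curve * (1 - preset$red_pigment *
                        exp(-(wavelengths - 550)^2 / (2 * 90^2)))
  }
  unname(curve)
}

#' Generate one synthetic reflectance spectrum
#'
#' The generative form is Beer--Lambert-like: a smooth baseline albedo
#' multiplied by exponentiated Gaussian absorption bands whose depths grow
#' linearly with the sugar content,
#' \deqn{R(\lambda) = B(\lambda) e^{-\sum_b d_b(x) G(\lambda; c_b, w_b)}
#'   (1 + m_0 + m_1 s(\lambda)) + a + \epsilon(\lambda)}
#' with \eqn{d_b(x) = \mathrm{base}_b + \mathrm{coupling}_b \cdot x} for
#' Brix \eqn{x}, a multiplicative scatter term with a random offset and
#' wavelength slope, an additive offset, and heteroscedastic noise with a
#' distinct standard deviation per detector region (350--1000,
#' 1000--1900, 1900--2500 nm). The result is clipped to (0, 1.2].
#'
#' @param brix Brix value of the sample.
#' @param preset a `variety_preset`.
#' @param wavelengths band-center grid in nm.
#' @param seed integer seed.
#' @return reflectance vector on `wavelengths`.
#' @export
generate_spectrum <- function(brix, preset, wavelengths = vnir_swir_grid(10),
                              seed = 1L) {
  bands <- preset$bands
  depth <- bands$base_depth + bands$sugar_coupling * brix
  bad <- which(depth < 0 | bands$width <= 0)
  check_that(length(bad) == 0,
             "band at %s nm drives reflectance out of range (negative depth or width)",
             paste(bands$center[bad], collapse = ", "))
  absorb <- rep(0, length(wavelengths))
  for (b in seq_len(nrow(bands))) {
    absorb <- absorb + depth[b] *
      exp(-(wavelengths - bands$center[b])^2 / (2 * bands$width[b]^2))
  }
  clean <- baseline_albedo(wavelengths, preset) * exp(-absorb)
  with_seed(seed, {
    m0 <- stats::rnorm(1, 0, preset$scatter["mult_sd"])
    m1 <- stats::rnorm(1, 0, preset$scatter["mult_sd"])
    slope <- (wavelengths - 1425) / 1075   # -1..1 across the grid
    offset <- stats::rnorm(1, 0, preset$scatter["add_sd"])
    region <- cut(wavelengths, c(-Inf, 1000, 1900, Inf), labels = FALSE)
    noise <- stats::rnorm(length(wavelengths)) * preset$noise_sd[region]
    r <- clean * (1 + m0 + m1 * slope) + offset + noise
    pmin(pmax(r, 1e-4), 1.2)
  })
}

#' Generator configuration
#'
#' @param n_per_variety samples per variety (default 240).
#' @param varieties variety names (must exist in `presets`).
#' @param grid_step 1 (native) or 10 (canonical modelling grid), in nm.
#' @param seed master seed.
#' @param presets preset list, defaults to [variety_presets()].
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_per_variety = 240L, varieties = NULL,
                             grid_step = 10, seed = 1L,
                             presets = variety_presets()) {
  varieties <- varieties %||% names(presets)
  check_that(all(varieties %in% names(presets)),
             "unknown varieties: %s",
             paste(setdiff(varieties, names(presets)), collapse = ", "))
  check_that(n_per_variety >= 1, "n_per_variety must be >= 1")
  check_that(grid_step %in% c(1, 10), "grid_step must be 1 or 10 nm")
  structure(list(n_per_variety = as.integer(n_per_variety),
                 varieties = varieties, grid_step = grid_step,
                 seed = as.integer(seed), presets = presets),
            class = "generator_config")
}

#' Generate a synthetic grape spectral library
#'
#' Draws `n_per_variety` samples per requested variety: Brix from the
#' preset's truncated normal, then a reflectance spectrum per sample via
#' [generate_spectrum()]. Sample ids are unique
#' (`<VAR>-0001`, ...), bunch labels cycle over simulated bunches, and
#' years alternate over the two campaign years. Identical configurations
#' (including the seed) reproduce the library exactly.
#'
#' @param config a [generator_config()].
#' @return a `spectral_library`.
#' @export
#' @examples
#' lib <- generate_library(generator_config(n_per_variety = 10, seed = 7))
#' n_samples(lib)  # 40
generate_library <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  wl <- vnir_swir_grid(config$grid_step)
  specs <- list(); metas <- list()
  for (v in config$varieties) {
    preset <- config$presets[[v]]
    n <- config$n_per_variety
    brix <- sample_brix(preset, n, seed = derive_seed(config$seed, "brix", v))
    mat <- matrix(0, n, length(wl))
    for (i in seq_len(n)) {
      mat[i, ] <- generate_spectrum(brix[i], preset, wl,
                                    seed = derive_seed(config$seed, "spec", v, i))
    }
    tag <- toupper(substr(gsub("[^A-Za-z]", "", v), 1, 3))
    metas[[v]] <- data.frame(
      sample_id = sprintf("%s-%04d", tag, seq_len(n)),
      variety = v,
      year = 2020L + (seq_len(n) %% 2L),
      bunch_label = sprintf("%s-B%02d", tag, ((seq_len(n) - 1L) %% 20L) + 1L),
      brix = brix, stringsAsFactors = FALSE)
    specs[[v]] <- mat
  }
  meta <- do.call(rbind, metas)
  spectral_library(do.call(rbind, specs), wl, brix = meta$brix,
                   sample_id = meta$sample_id, variety = meta$variety,
                   year = meta$year, bunch_label = meta$bunch_label)
}
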