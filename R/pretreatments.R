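#' Standard normal variate transform
#'
#' Centers a single spectrum and scales it to unit sample standard
#' deviation (ddof 1) — the classic per-spectrum scatter correction.
#'
#' @param spectrum numeric vector (length >= 2).
#' @return the transformed vector, with mean 0 and sample sd 1.
#' @export
#' @examples
#' snv(c(1, 2, 3))  # -1 0 1
snv <- function(spectrum) {
  check_that(length(spectrum) >= 2, "SNV needs at least 2 bands")
  s <- stats::sd(spectrum)
  check_that(s > 0, "zero-variance (constant) spectrum: SNV undefined")
  (spectrum - mean(spectrum)) / s
}

#' Pseudo-absorbance transform
#'
#' Converts reflectance to pseudo-absorbance, \eqn{A = -\log_{10}(R)},
#' motivated by the empirical Beer--Lambert law. Field spectra can contain
#' non-positive noise values; these are clamped to `floor` (with a warning)
#' rather than failing, so whole libraries remain usable.
#'
#' @param spectrum reflectance vector.
#' @param floor clamping floor applied before the logarithm.
#' @return absorbance vector.
#' @export
to_absorbance <- function(spectrum, floor = 1e-4) {
  n_bad <- sum(spectrum < floor)
  if (n_bad > 0) {
    warning(sprintf("%d reflectance value(s) below %g clamped before log10", n_bad, floor))
    spectrum <- pmax(spectrum, floor)
  }
  -log10(spectrum)
}

#' Savitzky--Golay filtering and derivatives
#'
#' Windowed local least-squares polynomial fit used for smoothing and
#' numerical derivatives of spectra. The settings used throughout this
#' workflow are a window of 5 bands and a polynomial order of 3.
#' Derivatives are scaled to per-nm units (the grid step is divided out),
#' so results are invariant to the sampling step. At the edges the
#' polynomial fitted to the nearest full window is evaluated asymmetrically,
#' keeping the output length equal to the input length.
#'
#' @param spectrum numeric vector, length >= `window`.
#' @param window odd window length (>= `poly + 1`).
#' @param poly polynomial order.
#' @param deriv derivative order, 0, 1 or 2 (<= `poly`).
#' @param step grid step in nm used to scale derivatives.
#' @return filtered (or differentiated) vector, same length as the input.
#' @export
savitzky_golay <- function(spectrum, window = 5, poly = 3, deriv = 0, step = 10) {
  check_that(window %% 2 == 1 && window >= poly + 1,
             "window must be odd and >= poly + 1")
  check_that(deriv %in% 0:2 && deriv <= poly, "deriv must be in {0,1,2} and <= poly")
  check_that(length(spectrum) >= window,
             "spectrum length (%d) < window (%d)", length(spectrum), window)
  out <- signal::sgolayfilt(spectrum, p = poly, n = window, m = deriv, ts = step)
  as.numeric(out)
}

# internal: upper convex hull of (x, y) by Andrew's monotone chain,
# retaining collinear points so CR is exactly 1 on straight segments
upper_hull_indices <- function(x, y) {
  n <- length(x)
  hull <- integer(0)
  cross <- function(o, a, b) {
    (x[a] - x[o]) * (y[b] - y[o]) - (y[a] - y[o]) * (x[b] - x[o])
  }
  for (i in seq_len(n)) {
    while (length(hull) >= 2 &&
           cross(hull[length(hull) - 1], hull[length(hull)], i) > 0) {
      hull <- hull[-length(hull)]
    }
    hull <- c(hull, i)
  }
  hull
}

#' Continuum removal
#'
#' Divides a reflectance spectrum by its upper convex hull (the
#' "continuum") evaluated on the wavelength grid, normalizing absorption
#' band depth. The output lies in (0, 1] and equals 1 at hull vertices,
#' including both endpoints; points exactly on a chord between hull
#' neighbours are kept on the hull (CR exactly 1 there).
#'
#' @param spectrum positive reflectance vector.
#' @param wavelengths band centers in nm (same length).
#' @return the continuum-removed spectrum.
#' @export
continuum_removal <- function(spectrum, wavelengths) {
  check_that(length(spectrum) >= 2, "continuum removal needs at least 2 bands")
  check_that(length(spectrum) == length(wavelengths), "grid length mismatch")
  check_that(all(spectrum > 0), "continuum removal requires positive reflectance")
  idx <- upper_hull_indices(wavelengths, spectrum)
  hull <- stats::approx(wavelengths[idx], spectrum[idx], xout = wavelengths)$y
  spectrum / hull
}

# --- pre-treatment chains ------------------------------------------------

chain_steps <- list(
  Ref = list(),
  Abs = list(fn = "abs"),
  SNV = list(fn = "snv"),
  SG1 = list(fn = "sg", deriv = 1),
  SG2 = list(fn = "sg", deriv = 2),
  CR  = list(fn = "cr")
)

parse_chain <- function(label) {
  tokens <- strsplit(label, "+", fixed = TRUE)[[1]]
  check_that(length(tokens) >= 1, "empty pre-treatment label")
  known <- c("Ref", "Abs", "SNV", "SG1", "SG2", "CR")
  bad <- setdiff(tokens, known)
  check_that(length(bad) == 0, "unknown pre-treatment label '%s' (unknown step: %s)",
             label, paste(bad, collapse = ", "))
  tokens
}

#' The nine spectral inputs
#'
#' Returns the registry of named pre-treatment chains that produce the
#' nine spectral inputs of the workflow: raw reflectance (`Ref`), its
#' scatter-corrected and first-derivative variants, the pseudo-absorbance
#' family up to the second derivative, and continuum removal.
#'
#' @return a named list of `pretreatment_chain` objects (label + ordered
#'   step tokens), with exactly nine entries:
#'   `Ref`, `Ref+SNV`, `Ref+SG1`, `Abs`, `Abs+SNV`, `Abs+SG1`,
#'   `Abs+SG1+SNV`, `Abs+SG2+SNV`, `CR`.
#' @export
pretreatment_registry <- function() {
  labels <- c("Ref", "Ref+SNV", "Ref+SG1", "Abs", "Abs+SNV", "Abs+SG1",
              "Abs+SG1+SNV", "Abs+SG2+SNV", "CR")
  out <- lapply(labels, function(l) {
    structure(list(label = l, steps = parse_chain(l)), class = "pretreatment_chain")
  })
  names(out) <- labels
  out
}

#' @export
print.pretreatment_chain <- function(x, ...) {
  cat("Pre-treatment chain:", x$label, "\n")
  invisible(x)
}

# internal: apply one step token to a spectra matrix (rows = samples)
apply_step <- function(token, spectra, wavelengths, sg_window = 5, sg_poly = 3) {
  step_nm <- if (length(wavelengths) > 1) wavelengths[2] - wavelengths[1] else 1
  switch(token,
    Ref = spectra,
    Abs = {
      n_bad <- sum(spectra < 1e-4)
      if (n_bad > 0)
        warning(sprintf("%d reflectance value(s) clamped to 1e-4 before log10", n_bad))
      -log10(pmax(spectra, 1e-4))
    },
    SNV = t(apply(spectra, 1, snv)),
    SG1 = t(apply(spectra, 1, savitzky_golay, window = sg_window, poly = sg_poly,
                  deriv = 1, step = step_nm)),
    SG2 = t(apply(spectra, 1, savitzky_golay, window = sg_window, poly = sg_poly,
                  deriv = 2, step = step_nm)),
    CR  = t(apply(spectra, 1, continuum_removal, wavelengths = wavelengths)),
    stop("unknown step token: ", token)
  )
}

#' Apply a named pre-treatment chain to a library
#'
#' Applies the ordered transforms of a chain label (e.g. `"Abs+SG1+SNV"`:
#' pseudo-absorbance, then first-derivative Savitzky--Golay, then SNV)
#' left-to-right to every spectrum. Brix and metadata are untouched. All
#' nine chains are per-spectrum (stateless), so applying them before fold
#' splitting leaks no cross-sample information.
#'
#' @param chain a chain label string (see [pretreatment_registry()]) or a
#'   `pretreatment_chain` object.
#' @param library a `spectral_library` in reflectance space.
#' @return a `spectral_library` whose `space` is the chain label.
#' @export
#' @examples
#' lib <- generate_library(generator_config(n_per_variety = 3,
#'                                          varieties = "Syrah", seed = 1))
#' d1 <- apply_chain("Ref+SG1", lib)
apply_chain <- function(chain, library) {
  stopifnot(inherits(library, "spectral_library"))
  label <- if (inherits(chain, "pretreatment_chain")) chain$label else chain
  tokens <- parse_chain(label)
  spectra <- library$spectra
  for (tok in tokens) {
    spectra <- apply_step(tok, spectra, library$wavelengths)
  }
  dimnames(spectra) <- dimnames(library$spectra)
  out <- library
  out$spectra <- spectra
  out$space <- label
  out
}
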