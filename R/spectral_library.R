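#' Canonical VNIR--SWIR wavelength grids
#'
#' The spectrometer emits reflectance on a 350--2500 nm grid with a 1 nm
#' step (2151 points). Modelling is done on the decimated 10 nm grid
#' \eqn{\{350 + 10k : k = 0, \dots, 215\}} (216 bands), which matches the
#' instrument's true optical resolution more closely than the native step.
#'
#' @param step grid step in nm (1 for the native grid, 10 for the
#'   canonical modelling grid).
#' @return numeric vector of band centers in nm.
#' @export
#' @examples
#' length(vnir_swir_grid(1))   # 2151
#' length(vnir_swir_grid(10))  # 216
vnir_swir_grid <- function(step = 10) {
  seq(350, 2500, by = step)
}

default_varieties <- function() {
  c("Chardonnay", "Malagouzia", "Sauvignon-Blanc", "Syrah")
}

validate_grid <- function(wavelengths) {
  check_that(is.numeric(wavelengths) && length(wavelengths) >= 1,
             "wavelength grid must be a non-empty numeric vector")
  check_that(all(is.finite(wavelengths)), "wavelength grid contains non-finite values")
  check_that(all(diff(wavelengths) > 0), "non-monotone grid: wavelengths must be strictly increasing")
  check_that(min(wavelengths) >= 350 && max(wavelengths) <= 2500,
             "wavelengths must lie within [350, 2500] nm")
  invisible(wavelengths)
}

#' Construct a grape spectral library
#'
#' A spectral library is the unit of modelling: an ordered set of samples
#' sharing one wavelength grid, each carrying a reflectance spectrum, the
#' ground-truth sugar content in degrees Brix, and collection metadata
#' (variety, year, bunch label).
#'
#' @param spectra numeric matrix, one row per sample, columns aligned to
#'   `wavelengths`.
#' @param wavelengths strictly increasing band centers in nm, within
#'   \[350, 2500\].
#' @param brix numeric vector of ground-truth degrees Brix, one per sample.
#' @param sample_id unique sample identifiers (default `"S0001"`, ...).
#' @param variety,year,bunch_label per-sample metadata (recycled if scalar).
#' @param brix_range plausibility window for Brix values; the default is
#'   the 0--32 Brix range of a field refractometer.
#' @param space label of the spectral space the values live in (`"Ref"`
#'   for raw reflectance; pre-treatment chains update it).
#' @return an object of class `spectral_library` with components
#'   `wavelengths`, `spectra` (matrix) and `samples` (metadata data frame).
#' @seealso [read_library()], [write_library()], [downsample()],
#'   [apply_chain()], [generate_library()]
#' @export
spectral_library <- function(spectra, wavelengths, brix,
                             sample_id = NULL, variety = "unknown",
                             year = NA_integer_, bunch_label = NA_character_,
                             brix_range = c(0, 32), space = "Ref") {
  spectra <- as.matrix(spectra)
  validate_grid(wavelengths)
  n <- nrow(spectra)
  check_that(ncol(spectra) == length(wavelengths),
             "reflectance length (%d) does not match grid length (%d)",
             ncol(spectra), length(wavelengths))
  check_that(is.numeric(spectra) && all(is.finite(spectra)),
             "non-numeric or non-finite reflectance values")
  check_that(length(brix) == n, "brix length (%d) != number of spectra (%d)",
             length(brix), n)
  bad <- which(!is.finite(brix) | brix < brix_range[1] | brix > brix_range[2])
  check_that(length(bad) == 0,
             "brix outside plausibility window [%g, %g] in rows: %s",
             brix_range[1], brix_range[2], paste(utils::head(bad, 10), collapse = ", "))
  if (is.null(sample_id)) sample_id <- sprintf("S%04d", seq_len(n))
  sample_id <- as.character(sample_id)
  check_that(length(sample_id) == n, "sample_id length mismatch")
  dup <- sample_id[duplicated(sample_id)]
  check_that(length(dup) == 0, "duplicate sample_id: %s",
             paste(unique(dup), collapse = ", "))
  samples <- data.frame(
    sample_id = sample_id,
    variety = rep_len(as.character(variety), n),
    year = rep_len(as.integer(year), n),
    bunch_label = rep_len(as.character(bunch_label), n),
    brix = as.numeric(brix),
    stringsAsFactors = FALSE
  )
  dimnames(spectra) <- list(sample_id, as.character(wavelengths))
  structure(
    list(wavelengths = as.numeric(wavelengths), spectra = spectra,
         samples = samples, space = space),
    class = "spectral_library"
  )
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf("Grape spectral library: %d samples x %d bands (%g-%g nm), space %s\n",
              nrow(x$spectra), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths), x$space))
  tab <- table(x$samples$variety)
  cat("  varieties:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  if (nrow(x$samples) > 0)
    cat(sprintf("  Brix: %.1f-%.1f (mean %.2f)\n",
                min(x$samples$brix), max(x$samples$brix), mean(x$samples$brix)))
  invisible(x)
}

#' Subset a spectral library by sample
#'
#' @param x a `spectral_library`.
#' @param i row (sample) index: integer, logical, or sample_id character.
#' @param ... unused.
#' @return a `spectral_library` with the selected samples.
#' @export
`[.spectral_library` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$samples$sample_id)
  structure(
    list(wavelengths = x$wavelengths,
         spectra = x$spectra[i, , drop = FALSE],
         samples = x$samples[i, , drop = FALSE],
         space = x$space),
    class = "spectral_library"
  )
}

#' Number of samples in a library
#' @param x a `spectral_library`.
#' @export
n_samples <- function(x) nrow(x$spectra)

library_meta_cols <- c("sample_id", "variety", "year", "bunch_label", "brix")

#' Read a grape spectral library from CSV
#'
#' The library CSV format has columns
#' `sample_id, variety, year, bunch_label, brix` followed by one numeric
#' column per wavelength, named by the integer band center in nm
#' (e.g. `350, 360, ..., 2500`), one row per sample, '.' decimal separator.
#'
#' @param path CSV file path.
#' @param brix_range plausibility window for Brix values (default the
#'   refractometer range \[0, 32\]).
#' @return a validated [spectral_library()]; row order is preserved.
#' @export
read_library <- function(path, brix_range = c(0, 32)) {
  check_that(file.exists(path), "file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  check_that(all(library_meta_cols %in% names(df)),
             "library CSV must start with columns: %s",
             paste(library_meta_cols, collapse = ", "))
  wl_cols <- setdiff(names(df), library_meta_cols)
  wl <- suppressWarnings(as.numeric(wl_cols))
  check_that(!anyNA(wl), "non-numeric wavelength column names: %s",
             paste(utils::head(wl_cols[is.na(wl)], 5), collapse = ", "))
  check_that(all(diff(wl) > 0), "non-monotone grid in CSV header")
  spectra <- as.matrix(df[, wl_cols, drop = FALSE])
  if (!is.numeric(spectra)) {
    bad_rows <- which(apply(df[, wl_cols, drop = FALSE], 1,
                            function(r) anyNA(suppressWarnings(as.numeric(r)))))
    stop(sprintf("non-numeric reflectance values in rows: %s",
                 paste(utils::head(bad_rows, 10), collapse = ", ")), call. = FALSE)
  }
  spectral_library(spectra, wl, brix = df$brix, sample_id = df$sample_id,
                   variety = df$variety, year = df$year,
                   bunch_label = df$bunch_label, brix_range = brix_range)
}

#' Write a grape spectral library to CSV
#'
#' Emits the library CSV format of [read_library()]. Brix is printed with
#' two decimals (the refractometer resolution is 0.2 Brix); reflectance is
#' printed with full double precision so that a read/write round trip is
#' the identity up to print precision.
#'
#' @param library a `spectral_library`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_library <- function(library, path) {
  stopifnot(inherits(library, "spectral_library"))
  meta <- library$samples
  meta$brix <- sprintf("%.2f", meta$brix)
  df <- cbind(meta, as.data.frame(library$spectra, check.names = FALSE))
  # integer-nm column names where the grid is integral
  wl <- library$wavelengths
  names(df) <- c(library_meta_cols,
                 ifelse(wl == round(wl), format(as.integer(round(wl))), as.character(wl)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Downsample a library to a coarser wavelength grid
#'
#' Reduces the native 1 nm grid to a coarser step (10 nm for the canonical
#' 216-band modelling grid). The default operator is a centered window
#' mean: the output value at band center \eqn{\lambda_k} is the mean of
#' input samples with wavelength in
#' \eqn{[\lambda_k - s/2, \lambda_k + s/2)} (intersected with the recorded
#' range), which suppresses noise consistent with the instrument's true
#' spectral resolution being coarser than the recording step. Plain
#' decimation (keeping the sample at each output center) is available for
#' sensitivity checks.
#'
#' @param library a `spectral_library`.
#' @param step output grid step in nm; must be a multiple of the input step
#'   and at least as large.
#' @param method `"mean"` (centered window mean, default) or
#'   `"decimate"` (subsample at the output centers).
#' @return a `spectral_library` on the grid
#'   \eqn{\{\min\lambda + s k\} \cap [\min\lambda, \max\lambda]};
#'   metadata and Brix are unchanged.
#' @export
#' @examples
#' lib <- generate_library(generator_config(n_per_variety = 3, grid_step = 1,
#'                                          varieties = "Syrah", seed = 1))
#' ds <- downsample(lib, 10)
#' length(ds$wavelengths)  # 216
downsample <- function(library, step = 10, method = c("mean", "decimate")) {
  stopifnot(inherits(library, "spectral_library"))
  method <- match.arg(method)
  wl <- library$wavelengths
  in_step <- unique(round(diff(wl), 9))
  check_that(length(in_step) == 1, "downsample requires an evenly spaced input grid")
  check_that(step >= in_step, "step (%g nm) smaller than input resolution (%g nm)",
             step, in_step)
  check_that(abs(step / in_step - round(step / in_step)) < 1e-9,
             "input grid step (%g) does not divide evenly into requested step (%g)",
             in_step, step)
  out_wl <- seq(min(wl), max(wl), by = step)
  if (method == "decimate") {
    idx <- match(out_wl, wl)
    out <- library$spectra[, idx, drop = FALSE]
  } else {
    bin <- floor((wl - min(wl) + step / 2) / step) + 1L
    keep <- bin >= 1L & bin <= length(out_wl)
    grp <- factor(bin[keep], levels = seq_along(out_wl))
    # window mean per output band, computed by grouped column means
    out <- t(rowsum(t(library$spectra[, keep, drop = FALSE]), grp)) /
      rep(as.vector(table(grp)), each = nrow(library$spectra))
  }
  spectral_library(out, out_wl, brix = library$samples$brix,
                   sample_id = library$samples$sample_id,
                   variety = library$samples$variety,
                   year = library$samples$year,
                   bunch_label = library$samples$bunch_label,
                   brix_range = c(-Inf, Inf), space = library$space)
}

#' Per-variety summary of the Brix ground truth
#'
#' Computes, per variety, the sample count, mean, standard deviation,
#' minimum, quartiles (linear-interpolation convention) and maximum of the
#' sugar content — the descriptive-statistics layout used for grape
#' spectral libraries.
#'
#' @param object a `spectral_library`.
#' @param ... unused.
#' @return a data frame of class `brix_summary`, one row per variety.
#' @export
summary.spectral_library <- function(object, ...) {
  check_that(nrow(object$samples) >= 1, "empty library")
  sp <- split(object$samples$brix, object$samples$variety)
  rows <- lapply(names(sp), function(v) {
    b <- sp[[v]]
    q <- quartiles(b)
    data.frame(variety = v, n = length(b), mean = mean(b),
               sd = if (length(b) > 1) stats::sd(b) else 0,
               min = min(b), q1 = q[1], median = q[2], q3 = q[3], max = max(b),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("brix_summary", "data.frame")
  out
}

#' @export
print.brix_summary <- function(x, ...) {
  cat("Brix content by variety\n")
  y <- as.data.frame(x)
  y[, -(1:2)] <- round(y[, -(1:2)], 2)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
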