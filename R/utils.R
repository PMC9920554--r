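#' Derive a reproducible child seed from a master seed and a label path
#'
#' Every source of randomness in the package (fold splitting, model fitting,
#' Hyperband sampling, the synthetic generator) draws its seed through this
#' function, so that one master seed makes a whole experiment reproducible
#' while keeping the random streams of different components decoupled.
#'
#' The derivation hashes the master seed together with the label path
#' (FNV-1a over the UTF-8 bytes of `"<master>/<label1>/<label2>/..."`,
#' reduced modulo a Mersenne prime) and always returns a positive integer
#' below 2^31.
#'
#' @param master integer master seed.
#' @param ... labels (coerced to character) identifying the consumer,
#'   e.g. `derive_seed(42, "outer-folds")`, `derive_seed(42, "refit", 3)`.
#' @return a positive integer seed.
#' @export
#' @examples
#' derive_seed(42, "outer-folds")
#' derive_seed(42, "cnn", 1)
derive_seed <- function(master, ...) {
  path <- paste(c(as.character(master), vapply(list(...), as.character, "")),
                collapse = "/")
  h <- 2166136261
  for (b in utf8ToInt(path)) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h %% 2147483629) + 1L
}

# internal: run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# internal: stopifnot-style check with a formatted message
check_that <- function(ok, fmt, ...) {
  if (!isTRUE(ok)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}

# internal: sample quantiles with the linear-interpolation ("type 7")
# convention used consistently for library summaries and RPIQ
quartiles <- function(x) {
  stats::quantile(x, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
}
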