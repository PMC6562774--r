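## Internal helpers: seeded stream derivation, leveled logging, rounding.

# Largest prime below 2^31; all derived seeds live in [0, .seed_mod).
.seed_mod <- 2147483647

#' Derive a child seed from a parent seed and a string tag
#'
#' Stage seeds (per segment, per fold, per training run) are derived
#' deterministically from one global seed so that a whole run is reproducible
#' from a single integer while independent stages still get distinct streams.
#' The derivation is a simple multiplicative string hash folded into the parent
#' seed modulo a Mersenne prime; all arithmetic stays below 2^53 so it is exact
#' in doubles.
#'
#' @param seed integer parent seed.
#' @param tag character scalar naming the stage/stream.
#' @return An integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @examples
#' derive_seed(42, "fold-1") != derive_seed(42, "fold-2")
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- 0
  for (b in utf8ToInt(as.character(tag))) h <- (h * 31 + b) %% .seed_mod
  as.integer(((abs(seed) %% .seed_mod) * 69069 + h * 2654435 + 1) %% (.seed_mod - 1))
}

## ---- leveled logging ------------------------------------------------------

.log_levels <- c(debug = 10L, info = 20L, warn = 30L, error = 40L, off = 99L)

#' Set or query the package log level
#'
#' Pipeline stages emit leveled log lines on stderr (stage, fold and epoch
#' where applicable). Level "warn" (the default) shows warnings such as
#' wavelet edge-effect notices; "info" adds per-stage progress; "off" silences
#' everything.
#'
#' @param level one of `"debug"`, `"info"`, `"warn"`, `"error"`, `"off"`,
#'   or `NULL` to query.
#' @return The current level, invisibly when setting.
#' @export
log_level <- function(level = NULL) {
  if (is.null(level)) {
    return(getOption("scalocnn.log_level", "warn"))
  }
  level <- match.arg(level, names(.log_levels))
  options(scalocnn.log_level = level)
  invisible(level)
}

.log <- function(level, ...) {
  threshold <- .log_levels[[getOption("scalocnn.log_level", "warn")]]
  if (.log_levels[[level]] >= threshold) {
    message(sprintf("[%s] %s", toupper(level), paste0(...)))
  }
  invisible(NULL)
}

log_info <- function(...) .log("info", ...)
log_warn <- function(...) .log("warn", ...)

## ---- numeric helpers ------------------------------------------------------

# Half-up rounding to `digits` decimals (base round() is banker's).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# clamp to [0, 1], preserving dim attributes
clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Validation failures are signalled with a dedicated condition class so the
# CLI can map them to exit code 2.
stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("scalocnn_validation_error", "error")))
}
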