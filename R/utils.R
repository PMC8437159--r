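#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; published survey tables are rounded
#' half-up, which is what all percentage formatting here uses.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Derive a child RNG seed from a parent seed and a stream label
#'
#' All randomness in the package flows from one user seed; per-site and
#' per-stage sub-streams are derived deterministically so stages can be rerun
#' in isolation. Kept below 2^31 so the result is always a valid R integer.
#'
#' @param seed parent integer seed.
#' @param label character scalar naming the sub-stream.
#' @return integer seed.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  bytes <- utf8ToInt(label)
  h <- as.double(seed %% 2147483647L)
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# internal: stop with a classed condition so callers can test error types
abort <- function(msg, class) {
  stop(structure(class = c(class, "dietshock_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
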