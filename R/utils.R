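#' Derive a reproducible sub-stream seed from a master seed
#'
#' Sub-stream seeds keep partial regeneration stable: cohort 3 gets the same
#' stream whether or not cohorts 1-2 were regenerated. The derivation is a
#' fixed affine hash folded into the positive 32-bit integer range.
#'
#' @param master integer master seed.
#' @param offset integer stream index (>= 0).
#' @return a positive integer usable with [set.seed()].
#' @export
derive_seed <- function(master, offset = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  m <- 2147483647 # 2^31 - 1
  s <- (abs(as.double(master)) %% m)
  s <- (s * 48271 + 7919 * (as.double(offset) + 1)) %% m
  as.integer(s) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with a consistent prefix for contract violations
abort_if <- function(cond, msg) {
  if (isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(NULL)
}
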