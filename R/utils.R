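# Internal helpers: seed management, rounding conventions, assertions.

#' Derive a sub-stream seed from a master seed
#'
#' All stochastic generators in the package are driven by a single integer
#' seed. Independent generator stages draw from sub-streams derived
#' deterministically from that master seed so that adding a stage never
#' perturbs the draws of another. The rule is
#' `(seed mod 10^6) * 2011 + stream * 7919`, which stays well below 2^31.
#'
#' @param seed master integer seed.
#' @param stream small non-negative integer identifying the sub-stream.
#' @return An integer seed.
#' @keywords internal
split_seed <- function(seed, stream) {
  seed <- as.integer(seed)
  (abs(seed) %% 1000000L) * 2011L + as.integer(stream) * 7919L
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

#' Round half away from zero
#'
#' Percentages reported by the package use commercial rounding (half away
#' from zero) rather than R's banker's rounding, so that e.g. a frequency of
#' 55.55\% prints as 55.6.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_away(0.45, 1)   # 0.5, where round() would give 0.4
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("`%s` must be a single finite number", name)
  }
  invisible(x)
}
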