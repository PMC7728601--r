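# Jukes-Cantor divergence correction.

#' Jukes-Cantor corrected divergence
#'
#' Converts an observed mismatch proportion `p` between two aligned sequences
#' into an estimated number of substitutions per site under the one-parameter
#' substitution model: `d = -(3/4) * log(1 - (4/3) p)`. The correction
#' accounts for multiple hits at the same site, so `d >= p` always, and it
#' saturates as `p` approaches 3/4 (random sequences).
#'
#' @param p observed mismatch proportion(s), in `[0, 0.75)`. `NA` values are
#'   propagated (used for windows with insufficient alignment).
#' @return Corrected divergence(s), substitutions/site.
#' @seealso [jukes_cantor_p()] for the inverse.
#' @export
#' @examples
#' jukes_cantor_distance(0.0139)
#' jukes_cantor_p(jukes_cantor_distance(0.0139))  # round trip
jukes_cantor_distance <- function(p) {
  if (is.logical(p) && all(is.na(p))) p <- as.numeric(p)
  if (!is.numeric(p)) stopf("`p` must be numeric")
  bad <- !is.na(p) & p < 0
  if (any(bad)) stopf("mismatch proportion must be non-negative")
  sat <- !is.na(p) & p >= 0.75
  if (any(sat)) {
    stopf("mismatch proportion >= 0.75: Jukes-Cantor correction saturated")
  }
  -0.75 * log1p(-4 * p / 3)
}

#' Invert the Jukes-Cantor correction
#'
#' @param d corrected divergence(s), substitutions/site, `>= 0`.
#' @return Expected mismatch proportion(s) `p = (3/4) (1 - exp(-4 d / 3))`.
#' @export
jukes_cantor_p <- function(d) {
  if (!is.numeric(d)) stopf("`d` must be numeric")
  if (any(!is.na(d) & d < 0)) stopf("divergence must be non-negative")
  0.75 * -expm1(-4 * d / 3)
}
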