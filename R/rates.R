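# Closed-form rate and age conversions.

#' Per-site yearly mutation rate from divergence and split time
#'
#' Converts an evolutionary distance `D` between two sister species
#' (substitutions/site) and their divergence time `T` (years) into a per-site
#' per-year substitution rate, mu = D / (2 T): the two lineages accumulate
#' substitutions independently, so the distance grows at twice the rate.
#' For the apple progenitors (D = 0.014, T = 1.8 million years) this yields
#' 3.9e-9 substitutions per site per year at two significant figures.
#'
#' @param D evolutionary distance between the two species, substitutions/site.
#' @param T_years divergence time in years.
#' @return Mutation rate in substitutions per site per year (full precision;
#'   round with `signif(mu, 2)` for display).
#' @export
#' @examples
#' signif(mutation_rate(0.014, 1.8e6), 2)  # 3.9e-09
mutation_rate <- function(D, T_years) {
  assert_scalar_number(D, "D")
  assert_scalar_number(T_years, "T_years")
  if (D < 0) stopf("`D` must be non-negative")
  if (T_years <= 0) stopf("`T_years` must be positive")
  D / (2 * T_years)
}

#' Insertion age of an LTR retrotransposon from twin-LTR divergence
#'
#' The two long terminal repeats of a retrotransposon are identical at
#' insertion and diverge at 2 mu per year afterwards, so an observed
#' divergence `d` dates the insertion at `d / (2 mu)` years.
#'
#' @param d divergence between the two LTRs, substitutions/site; must lie in
#'   `[0, 0.75)` (the Jukes-Cantor correction saturates at 0.75).
#' @param mu mutation rate, substitutions/site/year.
#' @return Age in years.
#' @export
#' @examples
#' ltr_insertion_age(0.0078, 3.9e-9)  # 1e6 years
ltr_insertion_age <- function(d, mu) {
  assert_scalar_number(mu, "mu")
  if (mu <= 0) stopf("`mu` must be positive")
  if (any(d < 0 | d >= 0.75)) stopf("`d` must lie in [0, 0.75)")
  d / (2 * mu)
}

#' Scale coalescent demographic output into years and individuals
#'
#' Sequentially Markovian coalescent programs report population history as a
#' scaled mutation parameter `theta0` (per analysis bin of `s` bp), scaled
#' times `t` (units of 2 N0 generations) and relative sizes `lambda`. With a
#' per-site yearly mutation rate `mu` and a generation time `g` (years) these
#' convert to absolute units as
#' `N0 = theta0 / (4 mu s)`, `years = 2 N0 g t` and `Ne = N0 lambda`.
#'
#' @param scaled data frame with columns `t` (scaled time) and `lambda`
#'   (relative population size).
#' @param theta0 scaled mutation parameter of the inference.
#' @param mu mutation rate, substitutions/site/year.
#' @param s bin size of the coalescent input, bp (often 100).
#' @param g generation time in years (default 7.5, the apple estimate).
#' @return Data frame with columns `years` and `Ne`, plus attribute `N0`.
#' @export
#' @examples
#' out <- scale_demography(data.frame(t = c(0.1, 1), lambda = c(1, 2)),
#'                         theta0 = 0.0012, mu = 3.9e-9, s = 100)
#' attr(out, "N0")
scale_demography <- function(scaled, theta0, mu, s = 100, g = 7.5) {
  if (!is.data.frame(scaled) || !all(c("t", "lambda") %in% names(scaled))) {
    stopf("`scaled` must be a data frame with columns `t` and `lambda`")
  }
  for (nm in c("theta0", "mu", "s", "g")) {
    v <- get(nm)
    assert_scalar_number(v, nm)
    if (v <= 0) stopf("`%s` must be positive", nm)
  }
  N0 <- theta0 / (4 * mu * s)
  out <- data.frame(
    years = 2 * N0 * g * scaled$t,
    Ne = N0 * scaled$lambda
  )
  attr(out, "N0") <- N0
  out
}
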