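# Population-genetic statistics: variant filters, allele frequencies,
# windowed diversity, distances and neighbor-joining.

#' GATK-style hard filter for variant records
#'
#' Applies the hard-filtering exclusion rules used for SNP discovery
#' (`QD < 2`, `QUAL < 60`, `SOR > 3`, `FS > 60`, `MQ < 40`,
#' `MQRankSum < -12.5`, `ReadPosRankSum < -8`) plus the allele-support rule
#' that both the reference and the alternative allele must be supported by
#' at least five reads. A missing annotation never fails its condition.
#'
#' @param records data frame with (any of the) columns `QD`, `QUAL`, `SOR`,
#'   `FS`, `MQ`, `MQRankSum`, `ReadPosRankSum`, `ref_depth`, `alt_depth`.
#'   Missing columns/`NA` values are treated as missing annotations.
#' @param min_allele_reads minimum read support per allele (default 5).
#' @return Character vector: `"pass"` or `"fail(<first failing rule>)"`.
#' @export
#' @examples
#' hard_filter_variant(data.frame(QD = 1.5, QUAL = 80))  # fail(QD)
hard_filter_variant <- function(records, min_allele_reads = 5) {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  get <- function(nm) {
    if (nm %in% names(records)) records[[nm]] else rep(NA_real_, n)
  }
  rules <- list(
    QD = get("QD") < 2,
    QUAL = get("QUAL") < 60,
    SOR = get("SOR") > 3,
    FS = get("FS") > 60,
    MQ = get("MQ") < 40,
    MQRankSum = get("MQRankSum") < -12.5,
    ReadPosRankSum = get("ReadPosRankSum") < -8,
    allele_support = get("ref_depth") < min_allele_reads |
      get("alt_depth") < min_allele_reads
  )
  out <- rep("pass", n)
  for (nm in rev(names(rules))) {
    bad <- !is.na(rules[[nm]]) & rules[[nm]]
    out[bad] <- sprintf("fail(%s)", nm)
  }
  out
}

#' Population-level site filter
#'
#' VCFtools-style site filtering: retain sites with minor-allele frequency
#' `>= maf` (computed over non-missing alleles), `QUAL >= min_qual` and at
#' most `max_missing_fraction` missing genotypes (`--max-missing 0.9`
#' semantics: at least 90% of genotypes present). All boundaries inclusive;
#' the filter is idempotent.
#'
#' @param gm a [genotype_matrix()].
#' @param maf minimum minor-allele frequency.
#' @param min_qual minimum site QUAL (skipped if `gm$qual` is `NULL`).
#' @param max_missing_fraction maximum fraction of missing genotypes.
#' @return A filtered [genotype_matrix()].
#' @export
population_filter <- function(gm, maf = 0.05, min_qual = 30,
                              max_missing_fraction = 0.10) {
  stopifnot(inherits(gm, "malus_genotypes"))
  g <- gm$genotypes
  if (nrow(g) == 0L) return(gm)
  n_miss <- rowSums(is.na(g))
  n_called <- ncol(g) - n_miss
  alt <- rowSums(g, na.rm = TRUE)
  freq <- ifelse(n_called > 0, alt / (2 * n_called), NA_real_)
  minor <- pmin(freq, 1 - freq)
  keep <- !is.na(minor) & minor >= maf &
    (n_miss / ncol(g)) <= max_missing_fraction
  if (!is.null(gm$qual)) keep <- keep & gm$qual >= min_qual
  genotype_matrix(g[keep, , drop = FALSE], gm$populations,
                  positions = gm$positions[keep],
                  chrom = gm$chrom[keep],
                  qual = if (is.null(gm$qual)) NULL else gm$qual[keep])
}

#' Alternative-allele frequency in a population
#'
#' Alt-allele count over twice the number of non-missing samples of the
#' population, as a percentage rounded to one decimal (half away from
#' zero) to match conventional reporting.
#'
#' @param gm a [genotype_matrix()].
#' @param population population label; `NULL` uses all samples.
#' @param site site index (row; default 1).
#' @param digits decimals of the reported percentage (`NULL` = unrounded).
#' @return Percentage in `[0, 100]`; `NA` if all genotypes missing.
#' @export
allele_frequency <- function(gm, population = NULL, site = 1, digits = 1) {
  stopifnot(inherits(gm, "malus_genotypes"))
  g <- site_genotypes(gm, population, site)
  g <- g[!is.na(g)]
  if (!length(g)) return(NA_real_)
  pct <- 100 * sum(g) / (2 * length(g))
  if (is.null(digits)) pct else round_half_away(pct, digits)
}

#' Genotype-class proportions in a population
#'
#' @inheritParams allele_frequency
#' @return Named percentages (hom_ref, het, hom_alt) over non-missing
#'   samples, rounded to one decimal (half away from zero).
#' @export
genotype_class_proportions <- function(gm, population = NULL, site = 1,
                                       digits = 1) {
  stopifnot(inherits(gm, "malus_genotypes"))
  g <- site_genotypes(gm, population, site)
  g <- g[!is.na(g)]
  if (!length(g)) return(c(hom_ref = NA_real_, het = NA_real_,
                           hom_alt = NA_real_))
  pct <- 100 * c(hom_ref = sum(g == 0), het = sum(g == 1),
                 hom_alt = sum(g == 2)) / length(g)
  if (is.null(digits)) pct else round_half_away(pct, digits)
}

site_genotypes <- function(gm, population, site) {
  cols <- if (is.null(population)) seq_along(gm$populations) else {
    if (!any(gm$populations == population)) {
      stopf("no samples in population '%s'", population)
    }
    which(gm$populations == population)
  }
  gm$genotypes[site, cols]
}

# per-site unbiased pairwise diversity: 2 p q * n_h / (n_h - 1) over the
# non-missing haplotypes of each site
site_pi <- function(g) {
  apply(g, 1L, function(row) {
    row <- row[!is.na(row)]
    nh <- 2 * length(row)
    if (nh < 2) return(0)
    p <- sum(row) / nh
    2 * p * (1 - p) * nh / (nh - 1)
  })
}

window_grid <- function(length_bp, window, step) {
  starts <- seq(0, max(0, length_bp - 1), by = step)
  data.frame(start = starts, end = pmin(starts + window, length_bp))
}

#' Windowed nucleotide diversity
#'
#' Computes pi in sliding windows: per site the unbiased pairwise-difference
#' estimator `2 p q n/(n-1)` over the `n` non-missing haplotypes, summed
#' over the sites falling in each window and divided by the full window
#' length in bp (VCFtools-style; set `per_accessible = TRUE` to divide by
#' accessible sites instead).
#'
#' @param gm a [genotype_matrix()] with site positions (1-based bp).
#' @param window window size, bp (default 20 kb).
#' @param step step size, bp (default 1 kb).
#' @param length_bp region length; defaults to the last site position.
#' @param per_accessible divide by number of sites instead of window bp.
#' @return Data frame: start, end (0-based half-open), n_segregating, pi.
#' @export
nucleotide_diversity_windows <- function(gm, window = 20000, step = 1000,
                                         length_bp = NULL,
                                         per_accessible = FALSE) {
  window_stats(gm, window, step, length_bp, per_accessible)[,
    c("start", "end", "n_segregating", "pi")]
}

#' Windowed Tajima's D (with pi)
#'
#' Standard Tajima (1989) statistic per window,
#' `D = (pi_total - S/a1) / sqrt(e1 S + e2 S (S-1))`, with constants from
#' the number of haplotypes. Sites with missing genotypes are excluded from
#' the D computation (pi for D is recomputed over complete sites) so that
#' the haplotype count is fixed. Windows with fewer than 3 segregating
#' sites, or fewer than 4 haplotypes, are reported as `NA` rather than
#' dropped.
#'
#' @inheritParams nucleotide_diversity_windows
#' @return Data frame: start, end, n_segregating, pi, tajima_d.
#' @export
tajimas_d_windows <- function(gm, window = 20000, step = 1000,
                              length_bp = NULL) {
  window_stats(gm, window, step, length_bp, per_accessible = FALSE)
}

tajima_constants <- function(n) {
  # n = number of haplotypes
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

window_stats <- function(gm, window, step, length_bp, per_accessible) {
  stopifnot(inherits(gm, "malus_genotypes"))
  if (ncol(gm$genotypes) == 0L) stopf("no samples")
  if (is.null(length_bp)) length_bp <- max(gm$positions, 1)
  grid <- window_grid(length_bp, window, step)
  pos <- gm$positions
  pi_site <- site_pi(gm$genotypes)
  seg <- pi_site > 0
  # complete-data sites, used for Tajima's D
  complete <- !apply(gm$genotypes, 1L, anyNA)
  nh <- 2 * ncol(gm$genotypes)
  const <- if (nh >= 4) tajima_constants(nh) else NULL
  out <- grid
  out$n_segregating <- NA_integer_
  out$pi <- NA_real_
  out$tajima_d <- NA_real_
  for (i in seq_len(nrow(grid))) {
    # positions are 1-based; window [start, end) covers pos in (start, end]
    inw <- pos > grid$start[i] & pos <= grid$end[i]
    out$n_segregating[i] <- sum(seg & inw)
    denom <- if (per_accessible) max(1L, sum(inw)) else
      (grid$end[i] - grid$start[i])
    out$pi[i] <- sum(pi_site[inw]) / denom
    cw <- complete & inw & seg
    S <- sum(cw)
    if (!is.null(const) && S >= 3) {
      pi_tot <- sum(pi_site[cw])
      denomD <- sqrt(const$e1 * S + const$e2 * S * (S - 1))
      out$tajima_d[i] <- (pi_tot - S / const$a1) / denomD
    }
  }
  out
}

#' Pairwise p-distance matrix from genotype dosages
#'
#' Distance between two diploid samples is the mean, over sites where both
#' are non-missing, of `|g_i - g_j| / 2` (half the allele-dosage
#' difference): identical genotypes contribute 0, opposite homozygotes 1.
#' Pairs with no shared non-missing site are `NA` with a warning.
#'
#' @param gm a [genotype_matrix()] (at least 2 samples).
#' @param labels optional sample labels (default `s1..sN`).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
p_distance_matrix <- function(gm, labels = NULL) {
  stopifnot(inherits(gm, "malus_genotypes"))
  g <- gm$genotypes
  n <- ncol(g)
  if (n < 2L) stopf("need at least 2 samples")
  if (is.null(labels)) labels <- paste0("s", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(g[, i]) & !is.na(g[, j])
      d[i, j] <- d[j, i] <- if (!any(ok)) NA_real_ else
        mean(abs(g[ok, i] - g[ok, j]) / 2)
    }
  }
  if (anyNA(d)) warning("sample pairs with no shared sites: NA distances",
                        call. = FALSE)
  d
}
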