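# Synthetic-data generators.
#
# Every generator is driven by a single integer seed through documented
# sub-streams (see split_seed), restores the caller's RNG state, and returns
# its ground truth alongside the data so downstream calls can be validated.

BASES <- c("A", "C", "G", "T")

#' Configuration for the hybrid-genome simulators
#'
#' Collects the parameters shared by [simulate_progenitor_pair()],
#' [simulate_hybrid_diploid()] and [simulate_window_observations()].
#'
#' Divergences are mismatch proportions between aligned sequences. The
#' defaults mirror the apple system: 0.014 between the two wild progenitor
#' species (*M. sieversii* vs *M. sylvestris*) and 0.006 within species
#' (a cultivar haplome vs the progenitor it descends from).
#'
#' @param genome_length total genome length, bp.
#' @param n_chromosomes number of chromosomes (equal sizes, last takes the
#'   remainder).
#' @param interspecific_divergence mismatch proportion between the two
#'   progenitor species.
#' @param intraspecific_divergence mismatch proportion between a hybrid
#'   haplome and its source progenitor (post-hybridization drift).
#' @param tract_length_mean mean ancestry-tract length, bp. Switching is
#'   memoryless: at each window boundary the origin flips with probability
#'   `window_size / tract_length_mean`, giving geometric tract lengths.
#'   `Inf` disables switching (single-tract haplomes).
#' @param window_size tract/window granularity, bp (default 50 kb, the
#'   painting window).
#' @param seed master integer seed.
#' @return An object of class `malus_sim_config` (a validated list).
#' @export
simulation_config <- function(genome_length = 1e7,
                              n_chromosomes = 1,
                              interspecific_divergence = 0.014,
                              intraspecific_divergence = 0.006,
                              tract_length_mean = 5e6,
                              window_size = 5e4,
                              seed = 1) {
  if (genome_length < 1) stopf("`genome_length` must be positive")
  if (n_chromosomes < 1 || n_chromosomes > genome_length) {
    stopf("`n_chromosomes` out of range")
  }
  for (d in c(interspecific_divergence, intraspecific_divergence)) {
    if (!is.finite(d) || d < 0) stopf("divergences must be non-negative")
    if (d >= 0.75) stopf("divergence >= 0.75: Jukes-Cantor correction undefined")
  }
  if (is.finite(tract_length_mean) && tract_length_mean < window_size) {
    stopf("`tract_length_mean` must be >= `window_size`")
  }
  if (window_size < 1) stopf("`window_size` must be positive")
  structure(
    list(
      genome_length = as.numeric(genome_length),
      n_chromosomes = as.integer(n_chromosomes),
      interspecific_divergence = interspecific_divergence,
      intraspecific_divergence = intraspecific_divergence,
      tract_length_mean = tract_length_mean,
      window_size = as.numeric(window_size),
      seed = as.integer(seed)
    ),
    class = "malus_sim_config"
  )
}

# chromosome lengths implied by a config
chrom_lengths_of <- function(config) {
  n <- config$n_chromosomes
  base <- floor(config$genome_length / n)
  lens <- rep(base, n)
  lens[n] <- config$genome_length - base * (n - 1)
  names(lens) <- paste0("chr", seq_len(n))
  lens
}

# mutate `n` distinct positions of an integer-coded sequence to a different base
mutate_sites <- function(seq_int, n) {
  if (n == 0L) return(list(seq = seq_int, pos = integer(0), to = integer(0)))
  pos <- sample.int(length(seq_int), n)
  to <- (seq_int[pos] - 1L + sample.int(3L, n, replace = TRUE)) %% 4L + 1L
  seq_int[pos] <- to
  list(seq = seq_int, pos = pos, to = to)
}

#' Simulate a diverged progenitor genome pair
#'
#' Draws a random ancestral genome and derives the two progenitor genomes
#' from it so that their realized p-distance is binomially distributed around
#' `interspecific_divergence`: the number of differing sites per chromosome
#' is a binomial draw, sites are chosen without replacement, and each
#' difference is assigned to one of the two descending lineages at random.
#'
#' @param config a [simulation_config()].
#' @return A list with elements `ancestral`, `sieversii`, `sylvestris` (each
#'   a named list of integer-coded chromosome sequences; see
#'   [seq_as_character()]), `substitution_map` (data frame: chrom, pos
#'   (1-based), lineage, from, to) and `config`.
#' @export
simulate_progenitor_pair <- function(config) {
  stopifnot(inherits(config, "malus_sim_config"))
  div <- config$interspecific_divergence
  lens <- chrom_lengths_of(config)
  with_seed(split_seed(config$seed, 1L), {
    ancestral <- lapply(lens, function(L) sample.int(4L, L, replace = TRUE))
    sie <- ancestral
    syl <- ancestral
    maps <- vector("list", length(lens))
    for (i in seq_along(lens)) {
      n_diff <- rbinom(1L, lens[i], div)
      if (n_diff == 0L) {
        maps[[i]] <- data.frame(
          chrom = character(0), pos = integer(0), lineage = character(0),
          from = character(0), to = character(0)
        )
        next
      }
      pos <- sample.int(lens[i], n_diff)
      lineage <- sample(c("sieversii", "sylvestris"), n_diff, replace = TRUE)
      old <- ancestral[[i]][pos]
      to <- (old - 1L + sample.int(3L, n_diff, replace = TRUE)) %% 4L + 1L
      is_sie <- lineage == "sieversii"
      sie[[i]][pos[is_sie]] <- to[is_sie]
      syl[[i]][pos[!is_sie]] <- to[!is_sie]
      maps[[i]] <- data.frame(
        chrom = names(lens)[i], pos = pos, lineage = lineage,
        from = BASES[old], to = BASES[to]
      )
    }
    list(
      ancestral = ancestral, sieversii = sie, sylvestris = syl,
      substitution_map = do.call(rbind, maps), config = config
    )
  })
}

#' Observed p-distance between two simulated genomes
#'
#' @param a,b genomes as returned by the simulators (named lists of
#'   integer-coded chromosomes of equal lengths).
#' @return Proportion of differing sites.
#' @export
sequence_p_distance <- function(a, b) {
  stopifnot(length(a) == length(b))
  diff <- sum(vapply(seq_along(a), function(i) sum(a[[i]] != b[[i]]), 0))
  diff / sum(vapply(a, length, 0))
}

#' Simulate a recombinant hybrid diploid
#'
#' Builds the two haplomes of a hybrid cultivar as mosaics of the two
#' progenitor genomes. Each haplome is tiled, independently of the other, by
#' ancestry tracts with geometrically distributed lengths (mean
#' `tract_length_mean`, granularity `window_size`), copying sequence from the
#' tract's progenitor. Independent intraspecific drift (mismatch proportion
#' `intraspecific_divergence`) is then applied to each haplome, so that even
#' same-origin haplome pairs show nonzero divergence.
#'
#' @param progenitors output of [simulate_progenitor_pair()].
#' @param config a [simulation_config()]; defaults to the one stored in
#'   `progenitors`.
#' @return A list with `haplome_A`, `haplome_B` (genomes), `truth` (data
#'   frame: haplome, chrom, start, end, origin; 0-based half-open tracts
#'   tiling each chromosome) and `config`.
#' @export
simulate_hybrid_diploid <- function(progenitors, config = progenitors$config) {
  stopifnot(inherits(config, "malus_sim_config"))
  lens <- vapply(progenitors$sieversii, length, 0)
  stopifnot(all(lens == vapply(progenitors$sylvestris, length, 0)))
  if (is.finite(config$tract_length_mean) &&
      config$tract_length_mean < config$window_size) {
    stopf("`tract_length_mean` must be >= `window_size`")
  }
  q <- if (is.finite(config$tract_length_mean)) {
    config$window_size / config$tract_length_mean
  } else 0
  origins <- c("sieversii", "sylvestris")
  with_seed(split_seed(config$seed, 2L), {
    haplomes <- list()
    truth <- list()
    for (h in c("A", "B")) {
      hap <- vector("list", length(lens))
      names(hap) <- names(lens)
      for (i in seq_along(lens)) {
        L <- lens[i]
        n_w <- ceiling(L / config$window_size)
        first <- sample.int(2L, 1L)
        flips <- if (n_w > 1L) runif(n_w - 1L) < q else logical(0)
        state <- (first - 1L + cumsum(c(0L, as.integer(flips)))) %% 2L + 1L
        r <- rle(origins[state])
        ends <- pmin(cumsum(r$lengths) * config$window_size, L)
        starts <- c(0, head(ends, -1))
        truth[[length(truth) + 1L]] <- data.frame(
          haplome = h, chrom = names(lens)[i],
          start = starts, end = ends, origin = r$values
        )
        seq_i <- progenitors$sieversii[[i]]
        syl_idx <- which(r$values == "sylvestris")
        for (j in syl_idx) {
          rng <- (starts[j] + 1):ends[j]
          seq_i[rng] <- progenitors$sylvestris[[i]][rng]
        }
        # independent post-hybridization drift
        n_mut <- rbinom(1L, L, config$intraspecific_divergence)
        hap[[i]] <- mutate_sites(seq_i, n_mut)$seq
      }
      haplomes[[h]] <- hap
    }
    list(
      haplome_A = haplomes$A, haplome_B = haplomes$B,
      truth = do.call(rbind, truth), config = config
    )
  })
}

#' Simulate an ancestry mosaic truth without sequences
#'
#' Draws the ancestry-tract structure of both haplomes of a hybrid diploid
#' (the same memoryless switching process as [simulate_hybrid_diploid()])
#' without generating any sequence, for use with the fast observation path
#' [simulate_window_observations()].
#'
#' @param config a [simulation_config()].
#' @return Tract data frame: haplome, chrom, start, end, origin; tracts tile
#'   every chromosome of both haplomes.
#' @export
simulate_mosaic_truth <- function(config) {
  stopifnot(inherits(config, "malus_sim_config"))
  lens <- chrom_lengths_of(config)
  q <- if (is.finite(config$tract_length_mean)) {
    config$window_size / config$tract_length_mean
  } else 0
  origins <- c("sieversii", "sylvestris")
  with_seed(split_seed(config$seed, 9L), {
    truth <- list()
    for (h in c("A", "B")) {
      for (i in seq_along(lens)) {
        L <- lens[i]
        n_w <- ceiling(L / config$window_size)
        first <- sample.int(2L, 1L)
        flips <- if (n_w > 1L) runif(n_w - 1L) < q else logical(0)
        state <- (first - 1L + cumsum(c(0L, as.integer(flips)))) %% 2L + 1L
        r <- rle(origins[state])
        ends <- pmin(cumsum(r$lengths) * config$window_size, L)
        truth[[length(truth) + 1L]] <- data.frame(
          haplome = h, chrom = names(lens)[i],
          start = c(0, head(ends, -1)), end = ends, origin = r$values
        )
      }
    }
    do.call(rbind, truth)
  })
}

#' Simulate window-level alignment observations from an ancestry truth
#'
#' Fast path that bypasses sequence simulation: for each painting window it
#' draws mismatch counts to both progenitor references binomially around the
#' divergence implied by the window's true ancestry composition. A window
#' with true origin *sieversii* has expected mismatch proportion
#' `intraspecific_divergence` against the *M. sieversii* reference and
#' `intraspecific + interspecific` against *M. sylvestris* (divergences of
#' independent branches add at these scales); mixed boundary windows use the
#' bp-weighted mixture.
#'
#' @param truth tract data frame as produced by [simulate_hybrid_diploid()]
#'   (columns haplome, chrom, start, end, origin); tracts must tile each
#'   chromosome.
#' @param config a [simulation_config()].
#' @param aligned_fraction fraction of each window that is alignable;
#'   windows with zero aligned length are emitted as unalignable.
#' @return A data frame of class `malus_windows` with one row per haplome
#'   and window: haplome, chrom, start, end, aligned_sie, mismatch_sie,
#'   aligned_syl, mismatch_syl.
#' @export
simulate_window_observations <- function(truth, config, aligned_fraction = 1) {
  stopifnot(inherits(config, "malus_sim_config"))
  if (aligned_fraction < 0 || aligned_fraction > 1) {
    stopf("`aligned_fraction` must be in [0, 1]")
  }
  intra <- config$intraspecific_divergence
  cross <- min(0.74, config$intraspecific_divergence +
                 config$interspecific_divergence)
  ws <- config$window_size
  with_seed(split_seed(config$seed, 3L), {
    out <- list()
    for (h in unique(truth$haplome)) {
      th <- truth[truth$haplome == h, ]
      for (chrom in unique(th$chrom)) {
        tc <- th[th$chrom == chrom, ]
        tc <- tc[order(tc$start), ]
        L <- max(tc$end)
        starts <- seq(0, L - 1, by = ws)
        ends <- pmin(starts + ws, L)
        # bp of each window that is sieversii-origin
        f_sie <- vapply(seq_along(starts), function(k) {
          ov <- pmin(tc$end, ends[k]) - pmax(tc$start, starts[k])
          sum(ov[ov > 0 & tc$origin == "sieversii"]) / (ends[k] - starts[k])
        }, 0)
        p_sie <- f_sie * intra + (1 - f_sie) * cross
        p_syl <- (1 - f_sie) * intra + f_sie * cross
        aligned <- round((ends - starts) * aligned_fraction)
        out[[length(out) + 1L]] <- data.frame(
          haplome = h, chrom = chrom, start = starts, end = ends,
          aligned_sie = aligned,
          mismatch_sie = rbinom(length(aligned), aligned, p_sie),
          aligned_syl = aligned,
          mismatch_syl = rbinom(length(aligned), aligned, p_syl)
        )
      }
    }
    res <- do.call(rbind, out)
    class(res) <- c("malus_windows", "data.frame")
    res
  })
}

#' Simulate block-level alignment observations from an ancestry truth
#'
#' Emits alignment blocks (the input of [project_to_windows()]) at a chosen
#' granularity, cut at tract boundaries, with mismatch counts drawn as in
#' [simulate_window_observations()]. Useful for exercising window-size and
#' alignment-length sensitivity scans.
#'
#' @inheritParams simulate_window_observations
#' @param haplome which haplome of `truth` to emit blocks for.
#' @param block_size block granularity, bp.
#' @return Data frame of alignment blocks: chrom, start, end, query
#'   (sieversii/sylvestris), aligned_columns, mismatches.
#' @export
simulate_alignment_blocks <- function(truth, config, haplome = "A",
                                      block_size = 1000,
                                      aligned_fraction = 1) {
  stopifnot(inherits(config, "malus_sim_config"))
  intra <- config$intraspecific_divergence
  cross <- min(0.74, config$intraspecific_divergence +
                 config$interspecific_divergence)
  th <- truth[truth$haplome == haplome, ]
  if (nrow(th) == 0L) stopf("no tracts for haplome %s", haplome)
  with_seed(split_seed(config$seed, 4L), {
    out <- list()
    for (i in seq_len(nrow(th))) {
      starts <- seq(th$start[i], th$end[i] - 1, by = block_size)
      ends <- pmin(starts + block_size, th$end[i])
      aligned <- round((ends - starts) * aligned_fraction)
      p_self <- intra
      p_other <- cross
      sie_first <- th$origin[i] == "sieversii"
      out[[length(out) + 1L]] <- data.frame(
        chrom = th$chrom[i],
        start = rep(starts, 2L), end = rep(ends, 2L),
        query = rep(c("sieversii", "sylvestris"), each = length(starts)),
        aligned_columns = rep(aligned, 2L),
        mismatches = c(
          rbinom(length(aligned), aligned, if (sie_first) p_self else p_other),
          rbinom(length(aligned), aligned, if (sie_first) p_other else p_self)
        )
      )
    }
    do.call(rbind, out)
  })
}

#' Simulate per-gene coverage with planted gene absences
#'
#' Generates the covered-fraction input of the presence/absence caller.
#' Coverage is simulated directly as the fraction of the coding region
#' covered at depth >= 2 (Beta-distributed around the depth-implied mean
#' under a Poisson depth model), not via read placement, since the PAV rule
#' consumes only that fraction. Genes planted absent draw their fraction
#' strictly below 0.20; planted present genes stay above `0.20 + margin`.
#'
#' @param gene_models data frame with columns `gene_id` and `cds_length`.
#' @param absence_matrix logical genes x accessions matrix (`TRUE` = planted
#'   absent), rownames matching `gene_id`.
#' @param mean_depth mean sequencing depth of present genes.
#' @param seed integer seed.
#' @param margin guaranteed separation of present genes from the 0.20
#'   absence threshold.
#' @return Data frame: gene_id, accession, cds_length, covered_bp,
#'   covered_fraction, truth_present.
#' @export
simulate_pav_coverage <- function(gene_models, absence_matrix,
                                  mean_depth = 20, seed = 1, margin = 0.05) {
  if (mean_depth <= 0) stopf("`mean_depth` must be positive")
  stopifnot(is.matrix(absence_matrix) || is.data.frame(absence_matrix))
  absence_matrix <- as.matrix(absence_matrix)
  stopifnot(nrow(absence_matrix) == nrow(gene_models))
  acc <- colnames(absence_matrix)
  if (is.null(acc)) acc <- paste0("acc", seq_len(ncol(absence_matrix)))
  with_seed(split_seed(seed, 5L), {
    n <- length(absence_matrix)
    absent <- as.vector(absence_matrix)
    f <- numeric(n)
    # fraction of bases at depth >= 2 under Poisson(mean_depth)
    base <- 1 - stats::ppois(1, mean_depth)
    conc <- 50
    f[!absent] <- pmin(1, pmax(0.2 + margin,
                               rbeta(sum(!absent), base * conc,
                                     (1 - base) * conc)))
    f[absent] <- 0.2 * rbeta(sum(absent), 2, 2)
    cds <- rep(gene_models$cds_length, times = length(acc))
    data.frame(
      gene_id = rep(gene_models$gene_id, times = length(acc)),
      accession = rep(acc, each = nrow(gene_models)),
      cds_length = cds,
      covered_bp = floor(f * cds),
      covered_fraction = floor(f * cds) / cds,
      truth_present = !absent
    )
  })
}

# fruit developmental stages, days after full bloom
DAF_STAGES <- c(11, 17, 29, 36, 43, 50, 57, 64, 71, 85, 99, 113, 127)

#' Simulate replicated allele-specific count tables
#'
#' Draws allele-A and allele-B read counts for each gene x developmental
#' stage x replicate cell from a negative-binomial model. Gene expression
#' levels are log-normal around `mean_depth`; the planted allelic log2 ratio
#' of each gene and stage is taken from `effect_spec`.
#'
#' @param n_genes number of genes.
#' @param stages stage labels (default the 13 apple fruit stages, in days
#'   after full bloom) or a single integer count.
#' @param replicates replicates per stage; scalar or vector along stages.
#' @param dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); 0 gives Poisson counts.
#' @param effect_spec numeric matrix `n_genes x n_stages` of true log2
#'   allelic ratios (A over B); default all zero (balanced).
#' @param mean_depth mean total count per gene and replicate.
#' @param seed integer seed.
#' @return List with `counts` (data frame: gene, stage, rep, count_A,
#'   count_B) and `truth` (the effect matrix used).
#' @export
simulate_ase_counts <- function(n_genes, stages = DAF_STAGES, replicates = 3,
                                dispersion = 0.05, effect_spec = NULL,
                                mean_depth = 100, seed = 1) {
  if (dispersion < 0) stopf("`dispersion` must be non-negative")
  if (length(stages) == 1L && is.numeric(stages) && stages > 1) {
    stages <- seq_len(stages)
  }
  n_stages <- length(stages)
  reps <- rep_len(replicates, n_stages)
  if (is.null(effect_spec)) {
    effect_spec <- matrix(0, n_genes, n_stages)
  }
  stopifnot(nrow(effect_spec) == n_genes, ncol(effect_spec) == n_stages)
  with_seed(split_seed(seed, 6L), {
    depth <- rlnorm(n_genes, meanlog = log(mean_depth), sdlog = 0.5)
    rows <- list()
    draw <- function(mu) {
      if (dispersion == 0) stats::rpois(length(mu), mu)
      else rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    }
    for (s in seq_len(n_stages)) {
      r <- 2^effect_spec[, s]
      mu_A <- depth * r / (1 + r)
      mu_B <- depth / (1 + r)
      for (k in seq_len(reps[s])) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = paste0("g", seq_len(n_genes)),
          stage = stages[s], rep = k,
          count_A = draw(mu_A), count_B = draw(mu_B)
        )
      }
    }
    list(counts = do.call(rbind, rows), truth = effect_spec)
  })
}

#' Construct a genotype matrix object
#'
#' Container for diploid genotype calls used by the population-genetic
#' functions: a sites x samples matrix of alt-allele dosages (0, 1, 2 or
#' `NA` for missing) with per-sample population labels.
#'
#' @param genotypes numeric matrix, sites x samples, values in
#'   `{0, 1, 2, NA}`.
#' @param populations character vector of population labels, one per sample.
#' @param positions optional 1-based site positions (bp).
#' @param chrom optional chromosome name(s) for the sites.
#' @param qual optional per-site QUAL values.
#' @return Object of class `malus_genotypes`.
#' @export
genotype_matrix <- function(genotypes, populations, positions = NULL,
                            chrom = NULL, qual = NULL) {
  genotypes <- as.matrix(genotypes)
  if (length(populations) != ncol(genotypes)) {
    stopf("`populations` must have one label per sample (column)")
  }
  ok <- genotypes %in% c(0, 1, 2) | is.na(genotypes)
  if (!all(ok)) stopf("genotype codes must be 0, 1, 2 or NA")
  if (is.null(positions)) positions <- seq_len(nrow(genotypes))
  if (length(positions) != nrow(genotypes)) {
    stopf("`positions` must have one entry per site")
  }
  if (!is.null(qual) && length(qual) != nrow(genotypes)) {
    stopf("`qual` must have one entry per site")
  }
  structure(
    list(genotypes = genotypes, populations = as.character(populations),
         positions = as.numeric(positions),
         chrom = if (is.null(chrom)) rep("chr1", nrow(genotypes)) else
           rep_len(chrom, nrow(genotypes)),
         qual = qual),
    class = "malus_genotypes"
  )
}

#' @export
print.malus_genotypes <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d sites x %d samples\n",
              nrow(x$genotypes), ncol(x$genotypes)))
  print(table(x$populations))
  invisible(x)
}

#' Simulate (or fix) a population genotype matrix
#'
#' Two modes. `"fixture"` reproduces exact genotype-class counts per
#' population (deterministic, for locus case studies such as the fruit
#' acidity *Ma1* SNP); `"hw"` draws Hardy-Weinberg genotypes at the
#' requested alt-allele frequencies.
#'
#' @param pop_spec data frame with one row per population. For fixture mode:
#'   columns `population`, `hom_ref`, `het`, `hom_alt` (counts). For HW mode:
#'   columns `population`, `n`, `freq` (alt-allele frequency).
#' @param mode `"fixture"` or `"hw"`.
#' @param n_sites number of (identically distributed) sites to emit.
#' @param seed integer seed (HW mode only).
#' @return A [genotype_matrix()].
#' @export
#' @examples
#' # the M. sylvestris Ma1 fixture: 11 samples, 1 heterozygote
#' gm <- simulate_genotype_matrix(
#'   data.frame(population = "sylvestris", hom_ref = 10, het = 1, hom_alt = 0))
simulate_genotype_matrix <- function(pop_spec,
                                     mode = c("fixture", "hw"),
                                     n_sites = 1, seed = 1) {
  mode <- match.arg(mode)
  if (mode == "fixture") {
    need <- c("population", "hom_ref", "het", "hom_alt")
    if (!all(need %in% names(pop_spec))) {
      stopf("fixture mode needs columns %s", paste(need, collapse = ", "))
    }
    geno_one <- unlist(lapply(seq_len(nrow(pop_spec)), function(i) {
      rep(c(0, 1, 2),
          times = c(pop_spec$hom_ref[i], pop_spec$het[i], pop_spec$hom_alt[i]))
    }))
    pops <- rep(pop_spec$population,
                times = pop_spec$hom_ref + pop_spec$het + pop_spec$hom_alt)
    if ("n" %in% names(pop_spec)) {
      tot <- pop_spec$hom_ref + pop_spec$het + pop_spec$hom_alt
      if (any(tot != pop_spec$n)) {
        stopf("genotype-class counts must sum to the population size")
      }
    }
    g <- matrix(rep(geno_one, each = n_sites), nrow = n_sites)
    return(genotype_matrix(g, pops, qual = rep(60, n_sites)))
  }
  need <- c("population", "n", "freq")
  if (!all(need %in% names(pop_spec))) {
    stopf("hw mode needs columns %s", paste(need, collapse = ", "))
  }
  with_seed(split_seed(seed, 7L), {
    pops <- rep(pop_spec$population, times = pop_spec$n)
    p <- rep(pop_spec$freq, times = pop_spec$n)
    g <- vapply(p, function(pi) rbinom(n_sites, 2L, pi), numeric(n_sites))
    g <- matrix(g, nrow = n_sites)
    genotype_matrix(g, pops, qual = rep(60, n_sites))
  })
}

#' Render an integer-coded genome as character sequences
#'
#' @param genome named list of integer-coded chromosomes (1..4 = A,C,G,T).
#' @return Named character vector of sequences.
#' @export
seq_as_character <- function(genome) {
  vapply(genome, function(s) paste(BASES[s], collapse = ""), "")
}
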