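# Allele-specific expression: haplome read assignment, phasing, the
# negative-binomial ASE test and the associated enrichment tests.

#' Assign reads to haplome alleles from alignment evidence
#'
#' A read uniquely aligned to the same chromosome in both haplomes is
#' assigned to the allele with the higher alignment score and no more
#' mismatches (at least one comparison strict); the rule is symmetric, and
#' everything else — including reads failing the unique/same-chromosome
#' requirement — is ambiguous (to be rescued by [snp_split_read()]).
#' With `strict_both = TRUE`, both the score and the mismatch comparison
#' must be strict.
#'
#' @param evidence data frame: `score_A`, `score_B`, `mm_A`, `mm_B` and
#'   optionally logical `uniquely_aligned_both`, `same_chromosome`.
#' @param strict_both require strict superiority in both score and
#'   mismatches.
#' @return Character vector: `"A"`, `"B"` or `"ambiguous"`.
#' @export
#' @examples
#' assign_read(data.frame(score_A = 60, score_B = 55, mm_A = 0, mm_B = 1))
assign_read <- function(evidence, strict_both = FALSE) {
  e <- evidence
  n <- nrow(e)
  eligible <- rep(TRUE, n)
  if ("uniquely_aligned_both" %in% names(e)) {
    eligible <- eligible & e$uniquely_aligned_both
  }
  if ("same_chromosome" %in% names(e)) {
    eligible <- eligible & e$same_chromosome
  }
  better <- function(s1, s2, m1, m2) {
    if (strict_both) s1 > s2 & m1 < m2
    else s1 >= s2 & m1 <= m2 & (s1 > s2 | m1 < m2)
  }
  out <- rep("ambiguous", n)
  out[eligible & better(e$score_A, e$score_B, e$mm_A, e$mm_B)] <- "A"
  out[eligible & better(e$score_B, e$score_A, e$mm_B, e$mm_A)] <- "B"
  out
}

#' Phase heterozygous SNPs onto the two haplomes, imputing missing sides
#'
#' A biallelic heterozygous call is phased directly when both haplome
#' alleles are observed and distinct. When only one haplome allele is
#' observed, the other haplome takes the remaining allele of the biallelic
#' call (`source = "imputed"`). Sites where both haplomes show the same
#' base, where an observed base matches neither call allele, or with no
#' haplome observation, are dropped.
#'
#' @param variants data frame: `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `hap_A`, `hap_B` (observed haplome bases, `NA` when unknown).
#' @return Data frame of phased SNPs: chrom, pos, allele_A, allele_B,
#'   source (`"direct"`/`"imputed"`).
#' @export
phase_and_impute <- function(variants) {
  v <- variants
  if (any(v$ref == v$alt)) stopf("ref and alt alleles must differ")
  known_A <- !is.na(v$hap_A)
  known_B <- !is.na(v$hap_B)
  valid <- function(x) is.na(x) | x == v$ref | x == v$alt
  ok <- valid(v$hap_A) & valid(v$hap_B)
  other <- function(x) ifelse(x == v$ref, v$alt, v$ref)
  allele_A <- allele_B <- rep(NA_character_, nrow(v))
  source <- rep(NA_character_, nrow(v))
  direct <- ok & known_A & known_B & v$hap_A != v$hap_B
  allele_A[direct] <- v$hap_A[direct]
  allele_B[direct] <- v$hap_B[direct]
  source[direct] <- "direct"
  impA <- ok & known_A & !known_B
  allele_A[impA] <- v$hap_A[impA]
  allele_B[impA] <- other(v$hap_A)[impA]
  source[impA] <- "imputed"
  impB <- ok & !known_A & known_B
  allele_B[impB] <- v$hap_B[impB]
  allele_A[impB] <- other(v$hap_B)[impB]
  source[impB] <- "imputed"
  keep <- !is.na(source)
  data.frame(chrom = v$chrom[keep], pos = v$pos[keep],
             allele_A = allele_A[keep], allele_B = allele_B[keep],
             source = source[keep])
}

#' Classify reads by phased-SNP votes
#'
#' Majority vote over the phased SNPs a read overlaps: each observed base
#' matching the A (resp. B) allele of the phased SNP at its position votes
#' for that haplome; bases matching neither allele are skipped. Ties and
#' reads with no informative overlap are ambiguous.
#'
#' @param read_observations data frame: `read_id`, `chrom`, `pos`, `base`.
#' @param phased_snps phased SNPs from [phase_and_impute()].
#' @return Data frame: read_id, votes_A, votes_B, assignment.
#' @export
snp_split_read <- function(read_observations, phased_snps) {
  ro <- read_observations
  key <- paste(ro$chrom, ro$pos)
  pkey <- paste(phased_snps$chrom, phased_snps$pos)
  m <- match(key, pkey)
  va <- !is.na(m) & ro$base == phased_snps$allele_A[m]
  vb <- !is.na(m) & ro$base == phased_snps$allele_B[m]
  ids <- unique(ro$read_id)
  votes_A <- as.vector(tapply(va, factor(ro$read_id, ids), sum))
  votes_B <- as.vector(tapply(vb, factor(ro$read_id, ids), sum))
  assignment <- ifelse(votes_A > votes_B, "A",
                       ifelse(votes_B > votes_A, "B", "ambiguous"))
  data.frame(read_id = ids, votes_A = votes_A, votes_B = votes_B,
             assignment = assignment)
}

#' Global and per-stage allele-assignment balance
#'
#' The ratio of reads assigned to haplome A over haplome B; unbiased
#' assignment yields ratios close to 1.
#'
#' @param counts allele count table: data frame with `stage`, `count_A`,
#'   `count_B` (gene rows with zero totals are ignored).
#' @return List with `overall` ratio and `per_stage` data frame; a zero B
#'   total yields `Inf` with a warning.
#' @export
assignment_balance <- function(counts) {
  cc <- counts[counts$count_A + counts$count_B > 0, ]
  if (nrow(cc) == 0L) stopf("empty count table")
  per_stage <- aggregate(cbind(count_A, count_B) ~ stage, cc, sum)
  per_stage$ratio <- per_stage$count_A / per_stage$count_B
  overall <- sum(cc$count_A) / sum(cc$count_B)
  if (!is.finite(overall) || any(!is.finite(per_stage$ratio))) {
    warning("zero assigned reads for one haplome: infinite ratio",
            call. = FALSE)
  }
  list(overall = overall, per_stage = per_stage)
}

# method-of-moments NB dispersion per gene, pooled over stage x allele cells
mom_dispersion <- function(counts) {
  est_cell <- function(x) {
    if (length(x) < 2L) return(NA_real_)
    m <- mean(x)
    if (m <= 0) return(NA_real_)
    (var(x) - m) / m^2
  }
  genes <- unique(counts$gene)
  disp <- vapply(split(counts, counts$gene), function(cg) {
    ests <- c(
      vapply(split(cg$count_A, cg$stage), est_cell, 0),
      vapply(split(cg$count_B, cg$stage), est_cell, 0)
    )
    ests <- ests[!is.na(ests)]
    if (!length(ests)) return(0)
    max(0, mean(ests))
  }, 0)
  disp[genes]
}

#' Test genes for allele-specific expression
#'
#' Per gene and developmental stage, a negative-binomial Wald test of the
#' allelic log ratio: gene-wise dispersion is estimated by the method of
#' moments across replicates (pooled over stages and alleles), the log
#' ratio of replicate-mean counts (0.5 pseudo-count) is compared to zero
#' with delta-method standard error `sqrt(((1/mu_A + phi) + (1/mu_B +
#' phi))/n)`, and p-values are Benjamini-Hochberg adjusted across genes
#' within each stage. A gene x stage is called significant when the
#' adjusted p-value is below `alpha` **and** the observed allelic ratio
#' exceeds `fold` (|log2 ratio| > log2(fold)).
#'
#' Gene x stage combinations where any replicate's total count (A + B) is
#' not above `min_total` are excluded. With a single replicate the test
#' falls back to an exact binomial test on the summed counts (with a
#' warning: no dispersion estimate is possible).
#'
#' @param counts data frame: gene, stage, rep, count_A, count_B.
#' @param min_total replicate-level total-count threshold (strict `>`).
#' @param fold fold-change required for a call (default 2).
#' @param alpha significance level on adjusted p-values.
#' @return Data frame of class `malus_ase`: gene, stage, n_reps,
#'   mean_A, mean_B, log2_ratio, p, padj, significant, dominant_allele.
#' @export
ase_test <- function(counts, min_total = 10, fold = 2, alpha = 0.05) {
  need <- c("gene", "stage", "rep", "count_A", "count_B")
  if (!all(need %in% names(counts))) {
    stopf("`counts` needs columns %s", paste(need, collapse = ", "))
  }
  ok_rep <- counts$count_A + counts$count_B > min_total
  keep_key <- !ave(ok_rep, counts$gene, counts$stage,
                   FUN = function(z) any(!z))
  cc <- counts[keep_key, , drop = FALSE]
  if (nrow(cc) == 0L) {
    return(structure(data.frame(
      gene = character(0), stage = numeric(0), n_reps = integer(0),
      mean_A = numeric(0), mean_B = numeric(0), log2_ratio = numeric(0),
      p = numeric(0), padj = numeric(0), significant = logical(0),
      dominant_allele = character(0)), class = c("malus_ase", "data.frame")))
  }
  disp <- mom_dispersion(cc)
  single_rep <- FALSE
  agg <- do.call(rbind, lapply(split(cc, list(cc$gene, cc$stage), drop = TRUE),
    function(d) {
      n <- nrow(d)
      mA <- mean(d$count_A)
      mB <- mean(d$count_B)
      lr <- log2((mA + 0.5) / (mB + 0.5))
      if (n == 1L) {
        single_rep <<- TRUE
        p <- binom.test(d$count_A, d$count_A + d$count_B, 0.5)$p.value
      } else {
        phi <- disp[[d$gene[1]]]
        se <- sqrt(((1 / (mA + 0.5) + phi) + (1 / (mB + 0.5) + phi)) / n)
        z <- log((mA + 0.5) / (mB + 0.5)) / se
        p <- 2 * pnorm(-abs(z))
      }
      data.frame(gene = d$gene[1], stage = d$stage[1], n_reps = n,
                 mean_A = mA, mean_B = mB, log2_ratio = lr, p = p)
    }))
  if (single_rep) {
    warning("single-replicate stages tested with an exact binomial test",
            call. = FALSE)
  }
  agg$padj <- ave(agg$p, agg$stage, FUN = function(p) p.adjust(p, "BH"))
  agg$significant <- agg$padj < alpha & abs(agg$log2_ratio) > log2(fold)
  agg$dominant_allele <- ifelse(!agg$significant, "none",
                                ifelse(agg$log2_ratio > 0, "A", "B"))
  rownames(agg) <- NULL
  class(agg) <- c("malus_ase", "data.frame")
  agg
}

#' @export
print.malus_ase <- function(x, ...) {
  cat(sprintf("ASE calls: %d gene x stage tests, %d significant (%d genes)\n",
              nrow(x), sum(x$significant),
              length(unique(x$gene[x$significant]))))
  NextMethod()
}

#' Allele-dominance profile of ASE genes across stages
#'
#' Classifies each gene by the pattern of its significant ASE calls:
#' `consistent_A`/`consistent_B` (same dominant allele at 2+ stages),
#' `switching` (dominant A at some stage and dominant B at another),
#' `single_stage` (ASE at exactly one stage) or `none`.
#'
#' @param ase_calls output of [ase_test()].
#' @return Data frame: gene, n_stages_ase, class.
#' @export
dominance_profile <- function(ase_calls) {
  res <- lapply(split(as.data.frame(ase_calls), ase_calls$gene), function(d) {
    sig <- d[d$significant, , drop = FALSE]
    nA <- sum(sig$dominant_allele == "A")
    nB <- sum(sig$dominant_allele == "B")
    cls <- if (nA > 0 && nB > 0) "switching"
      else if (nA + nB == 1L) "single_stage"
      else if (nA >= 2L) "consistent_A"
      else if (nB >= 2L) "consistent_B"
      else "none"
    data.frame(gene = d$gene[1], n_stages_ase = nrow(sig), class = cls)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Test over-representation of hybrid-ancestry gene pairs among ASE genes
#'
#' Two-sided Fisher's exact test of the 2x2 table of genes cross-classified
#' by allele ancestry (hybrid: the two alleles derive from different
#' progenitors) and ASE status.
#'
#' @param hybrid logical vector per gene: alleles of different progenitor
#'   ancestry.
#' @param ase logical vector per gene: gene shows ASE.
#' @return List: odds_ratio (sample estimate), p, table.
#' @export
ancestry_enrichment_test <- function(hybrid, ase) {
  if (length(hybrid) != length(ase)) stopf("inputs must have equal length")
  if (length(unique(hybrid)) < 2L || length(unique(ase)) < 2L) {
    stopf("degenerate input: both classifications need two levels")
  }
  tab <- table(factor(hybrid, c(TRUE, FALSE)), factor(ase, c(TRUE, FALSE)),
               dnn = c("hybrid", "ase"))
  ft <- fisher.test(tab)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(odds_ratio = unname(or), conditional_mle_or = unname(ft$estimate),
       p = ft$p.value, table = tab)
}

#' Test whether upstream SVs lie closer to ASE genes
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test comparing the
#' distances from genes to their nearest upstream structural variant
#' between ASE and non-ASE genes, with tie correction and normal
#' approximation for larger samples (exact enumeration when both groups
#' are small and tie-free). An all-tied input returns p = 1.
#'
#' @param distance non-negative distances, bp, one per gene.
#' @param ase logical ASE status per gene; both groups must be nonempty.
#' @return List: U (statistic for the ASE group), p.
#' @export
sv_proximity_test <- function(distance, ase) {
  if (any(distance < 0)) stopf("distances must be non-negative")
  x <- distance[ase]
  y <- distance[!ase]
  if (!length(x) || !length(y)) stopf("both groups must be nonempty")
  if (length(unique(c(x, y))) == 1L) {
    return(list(U = length(x) * length(y) / 2, p = 1))
  }
  wt <- suppressWarnings(wilcox.test(x, y, exact = (length(x) <= 20 &&
                                                      length(y) <= 20)))
  list(U = unname(wt$statistic), p = wt$p.value)
}
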