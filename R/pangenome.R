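# Pan-genome presence/absence variation: coverage-based calls, novel-segment
# extraction, pan/core accumulation curves, power-law fits and
# species-favored orthogroups.

#' Call gene presence/absence from coverage
#'
#' A gene is absent in an accession when strictly less than 20% of its
#' coding region is covered by at least two reads; exactly 20% is present.
#'
#' @param covered_bp bp of the coding region covered at depth >= 2.
#' @param cds_length coding-region length, bp (> 0).
#' @param threshold absence threshold on the covered fraction.
#' @return Logical vector: `TRUE` = present.
#' @export
#' @examples
#' call_gene_absence(c(150, 200, 1000), 1000)  # FALSE TRUE TRUE
call_gene_absence <- function(covered_bp, cds_length, threshold = 0.20) {
  if (any(cds_length <= 0)) stopf("`cds_length` must be positive")
  if (any(covered_bp < 0 | covered_bp > cds_length)) {
    stopf("`covered_bp` must lie in [0, cds_length]")
  }
  covered_bp / cds_length >= threshold
}

#' Build a PAV matrix from a coverage table
#'
#' @param coverage data frame with columns gene_id, accession, cds_length,
#'   covered_bp (e.g. from [simulate_pav_coverage()]).
#' @param threshold absence threshold (see [call_gene_absence()]).
#' @return Logical genes x accessions matrix (`TRUE` = present).
#' @export
pav_matrix <- function(coverage, threshold = 0.20) {
  present <- call_gene_absence(coverage$covered_bp, coverage$cds_length,
                               threshold)
  genes <- unique(coverage$gene_id)
  acc <- unique(coverage$accession)
  m <- matrix(NA, length(genes), length(acc), dimnames = list(genes, acc))
  m[cbind(match(coverage$gene_id, genes), match(coverage$accession, acc))] <-
    present
  if (anyNA(m)) stopf("coverage table must cover every gene x accession cell")
  m
}

#' Extract novel (unaligned) segments of a contig
#'
#' Returns the complement, within the contig, of the union of aligned
#' intervals whose identity reaches the cutoff (intervals below the cutoff
#' count as unaligned). Only segments strictly longer than `min_segment` bp
#' qualify as novel.
#'
#' @param contig_length contig length, bp.
#' @param aligned_intervals data frame: start, end (0-based half-open),
#'   identity (fraction in `[0,1]`).
#' @param min_segment minimum novel-segment length, bp (strict).
#' @param identity minimum alignment identity for an interval to mask.
#' @return Data frame of novel intervals: start, end, length.
#' @export
#' @examples
#' extract_novel_segments(2000, data.frame(start = 0, end = 1400,
#'                                         identity = 0.95))
extract_novel_segments <- function(contig_length, aligned_intervals,
                                   min_segment = 500, identity = 0.90) {
  ai <- aligned_intervals
  if (nrow(ai) > 0 && any(ai$start < 0 | ai$end > contig_length |
                          ai$end <= ai$start)) {
    stopf("aligned intervals out of contig bounds")
  }
  ai <- ai[ai$identity >= identity, , drop = FALSE]
  # union of qualifying intervals
  if (nrow(ai) > 0) {
    ai <- ai[order(ai$start), ]
    merged_s <- ai$start[1]; merged_e <- ai$end[1]
    us <- ue <- numeric(0)
    for (i in seq_len(nrow(ai))[-1]) {
      if (ai$start[i] <= merged_e) {
        merged_e <- max(merged_e, ai$end[i])
      } else {
        us <- c(us, merged_s); ue <- c(ue, merged_e)
        merged_s <- ai$start[i]; merged_e <- ai$end[i]
      }
    }
    us <- c(us, merged_s); ue <- c(ue, merged_e)
  } else {
    us <- ue <- numeric(0)
  }
  gaps_s <- c(0, ue)
  gaps_e <- c(us, contig_length)
  keep <- gaps_e - gaps_s > min_segment
  data.frame(start = gaps_s[keep], end = gaps_e[keep],
             length = (gaps_e - gaps_s)[keep])
}

#' Remove redundant segments by greedy identity clustering
#'
#' Greedy longest-first clustering: a segment is redundant when it is at
#' least `identity`-identical over at least `coverage` of its length to an
#' already retained segment (checked by local pairwise alignment after a
#' shared k-mer screen). This is a declared approximation of CD-HIT-style
#' redundancy removal, not a bit-compatible reimplementation.
#'
#' @param seqs named character vector of segment sequences.
#' @param identity identity cutoff (default 0.90).
#' @param coverage minimum fraction of the shorter segment that must align.
#' @param kmer k-mer size of the candidate screen.
#' @return Character vector of retained (nonredundant) sequences.
#' @export
dedupe_segments <- function(seqs, identity = 0.90, coverage = 0.90,
                            kmer = 11) {
  if (length(seqs) < 2L) return(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("seg", seq_along(seqs))
  ord <- order(-nchar(seqs))
  kmers <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < kmer) return(character(0))
    unique(substring(s, 1:(n - kmer + 1), kmer:n))
  })
  retained <- integer(0)
  for (i in ord) {
    redundant <- FALSE
    for (j in retained) {
      shared <- length(intersect(kmers[[i]], kmers[[j]]))
      if (shared < 0.5 * max(1, length(kmers[[i]]) * identity * coverage)) next
      aln <- Biostrings::pairwiseAlignment(seqs[i], seqs[j], type = "local")
      if (Biostrings::nmatch(aln) >= identity * coverage * nchar(seqs[i])) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) retained <- c(retained, i)
  }
  seqs[sort(retained)]
}

#' Collapse a gene-level PAV matrix to orthogroups
#'
#' An orthogroup is present in an accession if any of its member genes is
#' present (equivalently, absent only when no member passes the PAV
#' criterion). Genes missing from the map form singleton groups with a
#' warning.
#'
#' @param pav logical genes x accessions matrix (`TRUE` = present).
#' @param group_map data frame: gene_id, group_id (each gene in <= 1 group).
#' @return Logical groups x accessions matrix.
#' @export
orthogroup_pav <- function(pav, group_map) {
  genes <- rownames(pav)
  if (is.null(genes)) stopf("`pav` must have gene rownames")
  if (anyDuplicated(group_map$gene_id)) {
    stopf("each gene may belong to at most one group")
  }
  grp <- group_map$group_id[match(genes, group_map$gene_id)]
  unmapped <- is.na(grp)
  if (any(unmapped)) {
    warning(sprintf("%d unmapped gene(s) kept as singleton groups",
                    sum(unmapped)), call. = FALSE)
    grp[unmapped] <- genes[unmapped]
  }
  groups <- unique(grp)
  out <- matrix(FALSE, length(groups), ncol(pav),
                dimnames = list(groups, colnames(pav)))
  for (g in groups) {
    rows <- pav[grp == g, , drop = FALSE]
    out[g, ] <- colSums(rows) > 0
  }
  out
}

#' Pan- and core-genome accumulation curves
#'
#' For each number of accessions `N`, draws random accession orderings and
#' accumulates the union (pan) and intersection (core) of present genes
#' over the first `N` accessions; summarizes each `N` by the median and the
#' requested quantiles over orderings. `pan(1) == core(1)` within each
#' ordering, pan is monotone non-decreasing and core non-increasing.
#'
#' @param pav logical genes x accessions matrix.
#' @param n_permutations number of random orderings (>= 1).
#' @param seed integer seed.
#' @param probs quantiles reported besides the median.
#' @return Data frame: n_accessions, pan_median, pan_lo, pan_hi,
#'   core_median, core_lo, core_hi.
#' @export
sample_pan_core_curves <- function(pav, n_permutations = 100, seed = 1,
                                   probs = c(0.05, 0.95)) {
  if (n_permutations < 1) stopf("`n_permutations` must be >= 1")
  n_acc <- ncol(pav)
  if (n_acc < 2L) stopf("need at least 2 accessions")
  pan <- matrix(0L, n_permutations, n_acc)
  core <- matrix(0L, n_permutations, n_acc)
  with_seed(split_seed(seed, 8L), {
    for (p in seq_len(n_permutations)) {
      ord <- sample.int(n_acc)
      u <- pav[, ord[1]]
      s <- pav[, ord[1]]
      pan[p, 1] <- sum(u)
      core[p, 1] <- sum(s)
      for (k in seq_len(n_acc)[-1]) {
        u <- u | pav[, ord[k]]
        s <- s & pav[, ord[k]]
        pan[p, k] <- sum(u)
        core[p, k] <- sum(s)
      }
    }
  })
  data.frame(
    n_accessions = seq_len(n_acc),
    pan_median = apply(pan, 2, median),
    pan_lo = apply(pan, 2, quantile, probs[1]),
    pan_hi = apply(pan, 2, quantile, probs[2]),
    core_median = apply(core, 2, median),
    core_lo = apply(core, 2, quantile, probs[1]),
    core_hi = apply(core, 2, quantile, probs[2])
  )
}

#' Fit a power-law model to a pan- or core-genome curve
#'
#' Nonlinear least squares fit of `y = A N^gamma + C` (Tettelin-style) to
#' curve medians, grid-initialized over `gamma` (for each candidate gamma
#' the conditionally linear `A`, `C` are solved exactly, then the best start
#' is refined by Levenberg-Marquardt). Pan curves have `A > 0`; core curves
#' decay with `A < 0`. The pan-genome is flagged *closed* when `gamma < 1`
#' and the fitted slope at the largest sampled `N` falls below
#' `closed_slope` genes/accession.
#'
#' @param n vector of accession numbers (>= 4 support points).
#' @param y curve values (e.g. `pan_median`).
#' @param gamma_grid candidate exponents for initialization.
#' @param closed_slope slope threshold (genes per added accession) for the
#'   closedness flag.
#' @return Object of class `pan_curve_fit` with elements `A`, `gamma`, `C`,
#'   `residual_norm`, `closed`, `slope_at_max` and `data`.
#' @export
fit_power_law <- function(n, y, gamma_grid = seq(0.05, 1.5, by = 0.05),
                          closed_slope = 0.5) {
  if (length(n) < 4L || length(y) != length(n)) {
    stopf("need >= 4 support points with matching `n` and `y`")
  }
  if (diff(range(y)) < .Machine$double.eps * max(1, abs(y[1]))) {
    warning("flat curve: A ~ 0, exponent not identifiable", call. = FALSE)
    fit <- list(A = 0, gamma = 0, C = mean(y), residual_norm = 0)
  } else {
    best <- NULL
    for (g in gamma_grid) {
      X <- cbind(n^g, 1)
      cf <- tryCatch(qr.coef(qr(X), y), error = function(e) NULL)
      if (is.null(cf) || anyNA(cf)) next
      rss <- sum((y - X %*% cf)^2)
      if (is.null(best) || rss < best$rss) {
        best <- list(A = cf[1], gamma = g, C = cf[2], rss = rss)
      }
    }
    nls_fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A * n^gamma + C,
        start = list(A = best$A, gamma = best$gamma, C = best$C),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    fit <- if (is.null(nls_fit)) {
      list(A = best$A, gamma = best$gamma, C = best$C,
           residual_norm = sqrt(best$rss))
    } else {
      cf <- coef(nls_fit)
      list(A = unname(cf["A"]), gamma = unname(cf["gamma"]),
           C = unname(cf["C"]),
           residual_norm = sqrt(sum(stats::resid(nls_fit)^2)))
    }
  }
  slope <- fit$A * fit$gamma * max(n)^(fit$gamma - 1)
  structure(
    c(fit, list(
      closed = fit$gamma < 1 && abs(slope) < closed_slope,
      slope_at_max = slope,
      data = data.frame(n = n, y = y)
    )),
    class = "pan_curve_fit"
  )
}

#' @export
print.pan_curve_fit <- function(x, ...) {
  cat(sprintf("Power-law curve fit: y = %.4g * N^%.4g + %.4g\n",
              x$A, x$gamma, x$C))
  cat(sprintf("  residual norm %.4g | slope at N=%d: %.4g genes/accession | %s\n",
              x$residual_norm, max(x$data$n), x$slope_at_max,
              if (x$closed) "closed/saturated" else "open"))
  invisible(x)
}

#' @export
coef.pan_curve_fit <- function(object, ...) {
  c(A = object$A, gamma = object$gamma, C = object$C)
}

#' @export
predict.pan_curve_fit <- function(object, n = object$data$n, ...) {
  object$A * n^object$gamma + object$C
}

#' Plot a fitted pan/core curve
#'
#' Solid line over the sampled range, dashed extrapolation to twice the
#' largest sampled accession number.
#'
#' @param x a `pan_curve_fit`.
#' @param ... passed to [plot()].
#' @return Invisibly, `x`.
#' @export
plot.pan_curve_fit <- function(x, ...) {
  nmax <- max(x$data$n)
  plot(x$data$n, x$data$y, pch = 16, xlab = "accessions", ylab = "genes",
       xlim = c(1, 2 * nmax), ...)
  ns <- seq(1, nmax, length.out = 200)
  lines(ns, predict(x, ns), lwd = 2)
  ne <- seq(nmax, 2 * nmax, length.out = 100)
  lines(ne, predict(x, ne), lwd = 2, lty = 2)
  invisible(x)
}

#' Detect species-favored orthogroups from PAV patterns
#'
#' For every orthogroup and species pair, a 2x2 Fisher's exact test compares
#' presence/absence counts between the two species; p-values are
#' Benjamini-Hochberg adjusted per species pair (across groups). Categories
#' combine the significant pairs (adjusted p below `alpha`) with their
#' direction:
#' `dom_syl_vs_sie` (present enriched in both *M. domestica* and
#' *M. sylvestris* relative to *M. sieversii*), `dom_sie_vs_syl`
#' (the mirror image), `dom_only` (enriched in domestica against both wild
#' species, without either wild pattern) and `none`. Groups absent
#' everywhere are skipped.
#'
#' @param group_pav logical groups x accessions matrix.
#' @param species character vector of species labels per accession
#'   (`"domestica"`, `"sieversii"`, `"sylvestris"`).
#' @param alpha significance level on BH-adjusted p-values.
#' @return Data frame: group, presence count and total per species, the
#'   three pairwise odds ratios and adjusted p-values, and `category`.
#' @export
favored_orthogroups <- function(group_pav, species, alpha = 0.05) {
  if (length(species) != ncol(group_pav)) {
    stopf("`species` must label every accession column")
  }
  sp_levels <- c("domestica", "sieversii", "sylvestris")
  if (!all(species %in% sp_levels)) {
    stopf("species labels must be among %s", paste(sp_levels, collapse = ", "))
  }
  counts <- table(factor(species, sp_levels))
  if (sum(counts >= 2) < 2) stopf("need >= 2 species with >= 2 accessions")
  keep <- rowSums(group_pav) > 0
  skipped <- sum(!keep)
  if (skipped) {
    message(sprintf("%d group(s) absent everywhere skipped", skipped))
  }
  gp <- group_pav[keep, , drop = FALSE]
  pres <- vapply(sp_levels, function(s) {
    rowSums(gp[, species == s, drop = FALSE])
  }, numeric(nrow(gp)))
  tot <- as.numeric(counts)
  names(tot) <- sp_levels

  pairs <- list(c("domestica", "sieversii"), c("domestica", "sylvestris"),
                c("sieversii", "sylvestris"))
  res <- data.frame(group = rownames(gp),
                    pres_dom = pres[, "domestica"],
                    pres_sie = pres[, "sieversii"],
                    pres_syl = pres[, "sylvestris"],
                    n_dom = tot[["domestica"]],
                    n_sie = tot[["sieversii"]],
                    n_syl = tot[["sylvestris"]])
  for (pr in pairs) {
    a <- pres[, pr[1]]; na <- tot[[pr[1]]]
    b <- pres[, pr[2]]; nb <- tot[[pr[2]]]
    p <- vapply(seq_along(a), function(i) {
      fisher.test(matrix(c(a[i], na - a[i], b[i], nb - b[i]), 2))$p.value
    }, 0)
    orr <- (a + 0.5) / (na - a + 0.5) / ((b + 0.5) / (nb - b + 0.5))
    key <- paste0(substr(pr[1], 1, 3), "_", substr(pr[2], 1, 3))
    res[[paste0("or_", key)]] <- orr
    res[[paste0("padj_", key)]] <- p.adjust(p, "BH")
  }
  sig_ds <- res$padj_dom_sie < alpha
  sig_dy <- res$padj_dom_syl < alpha
  sig_sy <- res$padj_sie_syl < alpha
  up_ds <- res$or_dom_sie > 1   # domestica-enriched vs sieversii
  up_dy <- res$or_dom_syl > 1   # domestica-enriched vs sylvestris
  up_sy <- res$or_sie_syl > 1   # sieversii-enriched vs sylvestris
  category <- rep("none", nrow(res))
  category[sig_ds & up_ds & sig_sy & !up_sy] <- "dom_syl_vs_sie"
  dom_sie_vs_syl <- sig_dy & up_dy & sig_sy & up_sy & category == "none"
  category[dom_sie_vs_syl] <- "dom_sie_vs_syl"
  dom_only <- sig_ds & up_ds & sig_dy & up_dy & category == "none"
  category[dom_only] <- "dom_only"
  res$category <- category
  res
}
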