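# Window-based genome-ancestry painting.

#' Classification thresholds for ancestry painting
#'
#' The window classifier assigns a progenitor origin only when the smaller
#' of the two corrected divergences is below `max_assignable_divergence`
#' (strict) and the two divergences differ by more than `min_difference`
#' (strict); windows with less than `min_aligned` bp of alignment are never
#' classified. Defaults follow the apple analysis: 1.4% assignability bound
#' (the genome-wide mean of the larger divergence), 0.2% separation bound
#' (the lower bound of the mean divergence difference) and 100 bp minimum
#' alignment.
#'
#' @param max_assignable_divergence upper bound on the smaller divergence.
#' @param min_difference lower bound on `|d_sie - d_syl|`.
#' @param min_aligned minimum aligned bp for a window to carry a divergence.
#' @param both_bounded if `TRUE`, require both divergences (not only the
#'   smaller) to pass the assignability bound.
#' @return Object of class `malus_thresholds`.
#' @export
classification_thresholds <- function(max_assignable_divergence = 0.014,
                                      min_difference = 0.002,
                                      min_aligned = 100,
                                      both_bounded = FALSE) {
  if (max_assignable_divergence <= 0 || min_difference <= 0 || min_aligned <= 0) {
    stopf("all thresholds must be positive")
  }
  if (min_difference >= max_assignable_divergence) {
    stopf("`min_difference` must be smaller than `max_assignable_divergence`")
  }
  structure(
    list(max_assignable_divergence = max_assignable_divergence,
         min_difference = min_difference,
         min_aligned = min_aligned,
         both_bounded = isTRUE(both_bounded)),
    class = "malus_thresholds"
  )
}

# JC divergence columns for a window table; windows with aligned length
# below `min_aligned` or a saturated mismatch proportion get NA.
add_divergence <- function(windows, min_aligned) {
  jc_safe <- function(mism, aligned) {
    p <- ifelse(aligned >= min_aligned & aligned > 0, mism / aligned, NA_real_)
    p[!is.na(p) & p >= 0.75] <- NA_real_
    -0.75 * log1p(-4 * p / 3)
  }
  windows$d_sie <- jc_safe(windows$mismatch_sie, windows$aligned_sie)
  windows$d_syl <- jc_safe(windows$mismatch_syl, windows$aligned_syl)
  windows
}

#' Project alignment blocks onto non-overlapping genomic windows
#'
#' Sums aligned columns and mismatches of whole-genome alignment blocks over
#' a fixed window grid on the target genome. Blocks spanning a window
#' boundary are pro-rated by overlap length; pro-rated counts are rounded to
#' the nearest integer (half-up) at the window level. Jukes-Cantor
#' divergences to each progenitor are computed for windows with at least
#' `min_aligned` aligned bp; other windows carry `NA` (unalignable).
#'
#' Self-contradictory blocks (the same target bp aligned twice to the same
#' query) are resolved by first-block precedence with a warning: the later
#' block's overlapping portion is trimmed away.
#'
#' @param blocks data frame of alignment blocks: `chrom`, `start`, `end`
#'   (0-based half-open target coordinates), `query` (`"sieversii"` or
#'   `"sylvestris"`), `aligned_columns`, `mismatches`.
#' @param window_size window size, bp (default 50 kb).
#' @param min_aligned minimum aligned bp for a defined divergence.
#' @param chrom_lengths optional named vector of chromosome lengths; when
#'   given, the full grid is emitted (windows without alignment flagged
#'   unalignable), otherwise the grid extends to the last aligned block.
#' @return A `malus_windows` data frame: chrom, start, end, aligned_sie,
#'   mismatch_sie, aligned_syl, mismatch_syl, d_sie, d_syl.
#' @export
project_to_windows <- function(blocks, window_size = 50000, min_aligned = 100,
                               chrom_lengths = NULL) {
  if (window_size <= 0) stopf("`window_size` must be positive")
  need <- c("chrom", "start", "end", "query", "aligned_columns", "mismatches")
  if (!all(need %in% names(blocks))) {
    stopf("`blocks` needs columns %s", paste(need, collapse = ", "))
  }
  if (any(blocks$end <= blocks$start)) stopf("blocks must have end > start")
  if (any(blocks$mismatches > blocks$aligned_columns)) {
    stopf("mismatches cannot exceed aligned columns")
  }
  if (any(blocks$aligned_columns > blocks$end - blocks$start)) {
    stopf("aligned columns cannot exceed block span")
  }
  blocks <- blocks[order(blocks$query, blocks$chrom, blocks$start), ]
  # resolve double-counted target bp (same query): first-block precedence
  grp <- paste(blocks$query, blocks$chrom)
  clipped <- FALSE
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) < 2L) next
    run_end <- cummax(c(-Inf, blocks$end[idx[-length(idx)]]))
    lo <- pmax(blocks$start[idx], run_end)
    ov <- lo > blocks$start[idx]
    if (any(ov)) {
      clipped <- TRUE
      frac <- pmax(0, (blocks$end[idx] - lo)) /
        (blocks$end[idx] - blocks$start[idx])
      blocks$aligned_columns[idx] <- blocks$aligned_columns[idx] * frac
      blocks$mismatches[idx] <- blocks$mismatches[idx] * frac
      blocks$start[idx] <- pmin(lo, blocks$end[idx])
    }
  }
  if (clipped) {
    warning("overlapping blocks for the same query: ",
            "kept first-block precedence", call. = FALSE)
  }
  blocks <- blocks[blocks$end > blocks$start, ]

  pieces <- NULL
  if (nrow(blocks) > 0L) {
    fw <- floor(blocks$start / window_size)
    lw <- floor((blocks$end - 1) / window_size)
    nw <- lw - fw + 1L
    idx <- rep(seq_len(nrow(blocks)), nw)
    wi <- fw[idx] + sequence(nw) - 1L
    ws <- wi * window_size
    we <- ws + window_size
    ov <- pmin(blocks$end[idx], we) - pmax(blocks$start[idx], ws)
    frac <- ov / (blocks$end[idx] - blocks$start[idx])
    pieces <- data.frame(
      chrom = blocks$chrom[idx], wi = wi, query = blocks$query[idx],
      aligned = blocks$aligned_columns[idx] * frac,
      mism = blocks$mismatches[idx] * frac
    )
  }

  # window grid
  if (is.null(chrom_lengths)) {
    if (is.null(pieces)) stopf("empty block set and no `chrom_lengths`")
    chrom_lengths <- tapply(blocks$end, blocks$chrom, max)
  }
  grid <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    starts <- seq(0, chrom_lengths[[ch]] - 1, by = window_size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window_size, chrom_lengths[[ch]]))
  }))
  grid$wi <- grid$start / window_size

  take <- function(q, what) {
    if (is.null(pieces)) return(numeric(nrow(grid)))
    sub <- pieces[pieces$query == q, ]
    if (nrow(sub) == 0L) return(numeric(nrow(grid)))
    agg <- tapply(sub[[what]], paste(sub$chrom, sub$wi), sum)
    out <- agg[paste(grid$chrom, grid$wi)]
    out[is.na(out)] <- 0
    unname(out)
  }
  res <- data.frame(
    chrom = grid$chrom, start = grid$start, end = grid$end,
    aligned_sie = round(take("sieversii", "aligned")),
    mismatch_sie = floor(take("sieversii", "mism") + 0.5),
    aligned_syl = round(take("sylvestris", "aligned")),
    mismatch_syl = floor(take("sylvestris", "mism") + 0.5)
  )
  res$mismatch_sie <- pmin(res$mismatch_sie, res$aligned_sie)
  res$mismatch_syl <- pmin(res$mismatch_syl, res$aligned_syl)
  res <- add_divergence(res, min_aligned)
  class(res) <- c("malus_windows", "data.frame")
  res
}

#' Classify windows by progenitor origin
#'
#' Assigns each window to the progenitor with the smaller corrected
#' divergence, provided that divergence is below the assignability bound
#' (strict) and the two divergences are separated by more than the
#' difference bound (strict). Windows failing either rule, with equal
#' divergences, or with any undefined divergence are `"unclear"`. The
#' function is total and symmetric: swapping the two divergence vectors
#' swaps every non-unclear call.
#'
#' @param d_sie,d_syl corrected divergences to *M. sieversii* and
#'   *M. sylvestris* (`NA` = undefined).
#' @param thresholds a [classification_thresholds()].
#' @return Character vector of calls: `"sieversii"`, `"sylvestris"` or
#'   `"unclear"`.
#' @export
#' @examples
#' classify_window(0.008, 0.014, classification_thresholds())  # sieversii
classify_window <- function(d_sie, d_syl,
                            thresholds = classification_thresholds()) {
  stopifnot(inherits(thresholds, "malus_thresholds"))
  n <- max(length(d_sie), length(d_syl))
  d_sie <- rep_len(d_sie, n)
  d_syl <- rep_len(d_syl, n)
  call <- rep("unclear", n)
  ok <- !is.na(d_sie) & !is.na(d_syl)
  dmin <- pmin(d_sie, d_syl)
  dmax <- pmax(d_sie, d_syl)
  bound_ok <- if (thresholds$both_bounded) {
    dmax < thresholds$max_assignable_divergence
  } else {
    dmin < thresholds$max_assignable_divergence
  }
  assign <- ok & bound_ok & (abs(d_sie - d_syl) > thresholds$min_difference)
  call[assign & (d_sie < d_syl)] <- "sieversii"
  call[assign & (d_syl < d_sie)] <- "sylvestris"
  call
}

#' Paint a haplome: per-window origin calls and ancestry tracts
#'
#' Classifies every window of a haplome and merges maximal runs of identical
#' origin (including `"unclear"`) into ancestry tracts. Boundaries between
#' adjacent tracts of different non-unclear origin are candidate
#' recombination sites; each is reported as the (possibly zero-width)
#' interval between the last window of one origin and the first window of
#' the next, spanning any intervening unclear windows.
#'
#' @param windows a `malus_windows` table (from [project_to_windows()] or
#'   [simulate_window_observations()]); if divergence columns are missing
#'   they are computed using `thresholds$min_aligned`.
#' @param thresholds a [classification_thresholds()].
#' @return Object of class `malus_painting`: list with `windows` (input plus
#'   `call` column), `tracts` (chrom, start, end, origin, n_windows),
#'   `boundaries` (candidate recombination intervals) and `thresholds`.
#' @export
paint_haplome <- function(windows, thresholds = classification_thresholds()) {
  stopifnot(is.data.frame(windows))
  windows <- as.data.frame(windows)
  if (!all(c("d_sie", "d_syl") %in% names(windows))) {
    windows <- add_divergence(windows, thresholds$min_aligned)
  }
  windows <- windows[order(windows$chrom, windows$start), ]
  windows$call <- classify_window(windows$d_sie, windows$d_syl, thresholds)
  tracts <- list()
  bounds <- list()
  for (ch in unique(windows$chrom)) {
    wc <- windows[windows$chrom == ch, ]
    r <- rle(wc$call)
    iend <- cumsum(r$lengths)
    istart <- iend - r$lengths + 1L
    tracts[[ch]] <- data.frame(
      chrom = ch, start = wc$start[istart], end = wc$end[iend],
      origin = r$values, n_windows = r$lengths
    )
    # recombination candidates between consecutive classified tracts
    cl <- which(r$values != "unclear")
    if (length(cl) > 1L) {
      prev <- cl[-length(cl)]
      nxt <- cl[-1L]
      diff_origin <- r$values[prev] != r$values[nxt]
      if (any(diff_origin)) {
        bounds[[ch]] <- data.frame(
          chrom = ch,
          start = wc$end[iend[prev[diff_origin]]],
          end = wc$start[istart[nxt[diff_origin]]],
          left_origin = r$values[prev[diff_origin]],
          right_origin = r$values[nxt[diff_origin]]
        )
      }
    }
  }
  structure(
    list(
      windows = windows,
      tracts = do.call(rbind, unname(tracts)),
      boundaries = if (length(bounds)) do.call(rbind, unname(bounds)) else
        data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                   left_origin = character(0), right_origin = character(0)),
      thresholds = thresholds
    ),
    class = "malus_painting"
  )
}

#' @export
print.malus_painting <- function(x, ...) {
  f <- origin_fractions(x)
  cat(sprintf(
    "Ancestry painting: %d windows on %d chromosome(s), %d tracts\n",
    nrow(x$windows), length(unique(x$windows$chrom)), nrow(x$tracts)))
  cat(sprintf("  sieversii %.1f%% | sylvestris %.1f%% | unclear %.1f%%\n",
              100 * f[["sieversii"]], 100 * f[["sylvestris"]],
              100 * f[["unclear"]]))
  cat(sprintf("  %d candidate recombination boundaries\n", nrow(x$boundaries)))
  invisible(x)
}

#' Origin fractions of a painted haplome
#'
#' Fractions are bp-weighted over all windows (terminal partial windows
#' count their true length).
#'
#' @param painting a `malus_painting`.
#' @return Named numeric vector (sieversii, sylvestris, unclear), summing
#'   to 1.
#' @export
origin_fractions <- function(painting) {
  w <- painting$windows
  bp <- w$end - w$start
  tot <- sum(bp)
  vapply(c(sieversii = "sieversii", sylvestris = "sylvestris",
           unclear = "unclear"),
         function(o) sum(bp[w$call == o]) / tot, 0)
}

#' Summarize a diploid painting
#'
#' Combines the paintings of the two haplomes on a shared window grid into
#' per-haplome origin fractions and a per-window diploid classification:
#' a window is of *hybrid* origin when its two haplome calls are distinct
#' progenitors, *homozygous* when they agree, and *unresolved* when either
#' call is unclear. Fractions are bp-weighted; hybrid fractions are reported
#' both over all windows and over the windows classifiable in both haplomes.
#'
#' @param painting_A,painting_B `malus_painting` objects of the two haplomes
#'   on identical window grids.
#' @return Object of class `malus_painting_summary`: list with `haplomes`
#'   (per-haplome fraction table), `diploid` (named fractions: hybrid,
#'   homo_sie, homo_syl, unresolved), `diploid_classifiable` (fractions
#'   among windows classified in both haplomes) and `windows` (per-window
#'   diploid calls).
#' @export
summarize_painting <- function(painting_A, painting_B) {
  wA <- painting_A$windows
  wB <- painting_B$windows
  if (nrow(wA) != nrow(wB) ||
      !all(wA$chrom == wB$chrom & wA$start == wB$start & wA$end == wB$end)) {
    stopf("the two haplomes must be painted on identical window grids")
  }
  bp <- wA$end - wA$start
  tot <- sum(bp)
  state <- rep("unresolved", nrow(wA))
  both <- wA$call != "unclear" & wB$call != "unclear"
  state[both & wA$call != wB$call] <- "hybrid"
  state[both & wA$call == "sieversii" & wB$call == "sieversii"] <- "homo_sie"
  state[both & wA$call == "sylvestris" & wB$call == "sylvestris"] <- "homo_syl"
  dip <- vapply(c(hybrid = "hybrid", homo_sie = "homo_sie",
                  homo_syl = "homo_syl", unresolved = "unresolved"),
                function(s) sum(bp[state == s]) / tot, 0)
  dip_cl <- if (any(both)) {
    vapply(c(hybrid = "hybrid", homo_sie = "homo_sie", homo_syl = "homo_syl"),
           function(s) sum(bp[both & state == s]) / sum(bp[both]), 0)
  } else c(hybrid = NA_real_, homo_sie = NA_real_, homo_syl = NA_real_)
  haps <- rbind(
    data.frame(haplome = "A", t(origin_fractions(painting_A))),
    data.frame(haplome = "B", t(origin_fractions(painting_B)))
  )
  structure(
    list(haplomes = haps, diploid = dip, diploid_classifiable = dip_cl,
         windows = data.frame(chrom = wA$chrom, start = wA$start,
                              end = wA$end, call_A = wA$call,
                              call_B = wB$call, state = state)),
    class = "malus_painting_summary"
  )
}

#' @export
print.malus_painting_summary <- function(x, ...) {
  cat("Diploid ancestry summary (bp fractions)\n")
  print(x$haplomes, row.names = FALSE)
  cat(sprintf(
    "  hybrid %.1f%% | homo sieversii %.1f%% | homo sylvestris %.1f%% | unresolved %.1f%%\n",
    100 * x$diploid[["hybrid"]], 100 * x$diploid[["homo_sie"]],
    100 * x$diploid[["homo_syl"]], 100 * x$diploid[["unresolved"]]))
  if (!is.na(x$diploid_classifiable[["hybrid"]])) {
    cat(sprintf("  hybrid among classifiable windows: %.1f%%\n",
                100 * x$diploid_classifiable[["hybrid"]]))
  }
  invisible(x)
}

#' Sensitivity of origin fractions to window size and alignment cutoff
#'
#' Re-projects the same alignment blocks at every combination of window size
#' and minimum-alignment cutoff, paints each projection and tabulates the
#' origin fractions. The attribute `max_range` reports the largest spread
#' (max minus min, in fraction units) of the sieversii/sylvestris fractions
#' across combinations.
#'
#' @param blocks alignment blocks (see [project_to_windows()]).
#' @param window_sizes vector of window sizes, bp.
#' @param min_aligned_list vector of minimum-alignment cutoffs, bp.
#' @param thresholds a [classification_thresholds()] (its `min_aligned` is
#'   overridden per combination).
#' @param chrom_lengths optional named chromosome lengths.
#' @return Data frame with one row per combination: window_size,
#'   min_aligned, fraction_sieversii, fraction_sylvestris, fraction_unclear;
#'   attribute `max_range` as above.
#' @export
sensitivity_scan <- function(blocks,
                             window_sizes = c(5, 10, 20, 30, 40, 50, 60, 70) * 1000,
                             min_aligned_list = c(100, 300, 500, 1000),
                             thresholds = classification_thresholds(),
                             chrom_lengths = NULL) {
  if (!length(window_sizes) || !length(min_aligned_list)) {
    stopf("`window_sizes` and `min_aligned_list` must be nonempty")
  }
  rows <- list()
  for (ws in window_sizes) {
    for (ma in min_aligned_list) {
      th <- classification_thresholds(
        thresholds$max_assignable_divergence, thresholds$min_difference,
        ma, thresholds$both_bounded)
      wins <- project_to_windows(blocks, window_size = ws, min_aligned = ma,
                                 chrom_lengths = chrom_lengths)
      f <- origin_fractions(paint_haplome(wins, th))
      rows[[length(rows) + 1L]] <- data.frame(
        window_size = ws, min_aligned = ma,
        fraction_sieversii = f[["sieversii"]],
        fraction_sylvestris = f[["sylvestris"]],
        fraction_unclear = f[["unclear"]]
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "max_range") <- max(
    diff(range(out$fraction_sieversii)),
    diff(range(out$fraction_sylvestris))
  )
  out
}

#' Assign an origin to genomic regions from ancestry tracts
#'
#' Each region takes the origin covering the plurality of its bp; bp not
#' covered by any tract count as unclear, and ties or unclear-dominated
#' regions are `"unclear"`. Regions on chromosomes absent from the tract set
#' are skipped with a warning.
#'
#' @param regions data frame: chrom, start, end (0-based half-open).
#' @param tracts tract data frame (chrom, start, end, origin), e.g. from a
#'   [paint_haplome()] result.
#' @return `regions` with an added `origin` column (skipped regions absent).
#' @export
intersect_regions_with_ancestry <- function(regions, tracts) {
  known <- regions$chrom %in% unique(tracts$chrom)
  if (any(!known)) {
    warning(sprintf("%d region(s) on unknown chromosomes skipped",
                    sum(!known)), call. = FALSE)
  }
  regions <- regions[known, , drop = FALSE]
  origin <- character(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    tc <- tracts[tracts$chrom == regions$chrom[i], ]
    ov <- pmin(tc$end, regions$end[i]) - pmax(tc$start, regions$start[i])
    keep <- ov > 0
    bp <- c(sieversii = 0, sylvestris = 0, unclear = 0)
    for (o in names(bp)) bp[o] <- sum(ov[keep & tc$origin == o])
    bp["unclear"] <- bp[["unclear"]] +
      (regions$end[i] - regions$start[i]) - sum(ov[keep])
    top <- names(bp)[bp == max(bp)]
    origin[i] <- if (length(top) > 1L || top == "unclear") "unclear" else top
  }
  regions$origin <- origin
  regions
}

#' Plot divergence tracks of a painted haplome
#'
#' Per-window corrected divergences to the two progenitors along one
#' chromosome, with tricube-weighted local-linear (loess) smoothing for
#' display. Smoothing never enters classification, which operates on raw
#' windows.
#'
#' @param x a `malus_painting`.
#' @param chrom chromosome to plot (default the first).
#' @param span loess span as a fraction of windows.
#' @param ... passed to [plot()].
#' @return Invisibly, `x`.
#' @export
plot.malus_painting <- function(x, chrom = NULL, span = 0.02, ...) {
  w <- x$windows
  if (is.null(chrom)) chrom <- w$chrom[1]
  w <- w[w$chrom == chrom, ]
  mid <- (w$start + w$end) / 2
  plot(mid, w$d_sie, col = "forestgreen", pch = 16, cex = 0.4,
       xlab = sprintf("%s position (bp)", chrom),
       ylab = "JC divergence",
       ylim = range(c(w$d_sie, w$d_syl), na.rm = TRUE), ...)
  points(mid, w$d_syl, col = "purple", pch = 16, cex = 0.4)
  for (col_d in list(c("d_sie", "forestgreen"), c("d_syl", "purple"))) {
    ok <- !is.na(w[[col_d[1]]])
    if (sum(ok) > 10) {
      sp <- max(span, 10 / sum(ok))
      fit <- loess(w[[col_d[1]]][ok] ~ mid[ok], span = sp, degree = 1,
                   family = "gaussian")
      lines(mid[ok], predict(fit), col = col_d[2], lwd = 2)
    }
  }
  abline(h = x$thresholds$max_assignable_divergence, lty = 2, col = "grey40")
  legend("topright", c("vs sieversii", "vs sylvestris"),
         col = c("forestgreen", "purple"), pch = 16, bty = "n")
  invisible(x)
}
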