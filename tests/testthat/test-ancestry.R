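th <- classification_thresholds()

test_that("block projection sums, pro-rates and applies the alignment cutoff", {
  blocks <- data.frame(
    chrom = "chr1", start = 0, end = 50000,
    query = c("sieversii", "sylvestris"),
    aligned_columns = c(50000, 50000), mismatches = c(500, 700)
  )
  w <- project_to_windows(blocks, window_size = 50000)
  expect_equal(nrow(w), 1)
  expect_equal(w$mismatch_sie / w$aligned_sie, 0.01)
  expect_equal(w$d_sie, jukes_cantor_distance(0.01))

  # a window with < 100 aligned bp has undefined divergence
  short <- data.frame(chrom = "chr1", start = 0, end = 80,
                      query = "sieversii", aligned_columns = 80,
                      mismatches = 1)
  w2 <- project_to_windows(short, window_size = 50000, min_aligned = 100)
  expect_true(is.na(w2$d_sie))

  # empty block set on a known grid: every window unalignable
  w3 <- project_to_windows(blocks[0, ], window_size = 1e4,
                           chrom_lengths = c(chr1 = 3e4))
  expect_equal(nrow(w3), 3)
  expect_true(all(is.na(w3$d_sie) & is.na(w3$d_syl)))

  # pro-rating splits a boundary-spanning block by overlap length
  span <- data.frame(chrom = "chr1", start = 40000, end = 60000,
                     query = "sieversii", aligned_columns = 20000,
                     mismatches = 200)
  w4 <- project_to_windows(span, window_size = 50000,
                           chrom_lengths = c(chr1 = 1e5))
  expect_equal(w4$aligned_sie, c(10000, 10000))
  expect_equal(w4$mismatch_sie, c(100, 100))

  # same target bp aligned twice to one query: first block wins, warning
  dup <- data.frame(chrom = "chr1", start = c(0, 0), end = c(1000, 1000),
                    query = "sieversii", aligned_columns = c(1000, 1000),
                    mismatches = c(10, 500))
  expect_warning(w5 <- project_to_windows(dup, window_size = 1000), "first-block")
  expect_equal(w5$mismatch_sie, 10)
})

test_that("window classification applies both bounds strictly and symmetrically", {
  expect_equal(classify_window(0.008, 0.014, th), "sieversii")
  expect_equal(classify_window(0.010, 0.0115, th), "unclear")  # diff <= 0.2%
  expect_equal(classify_window(0.01, 0.01, th), "unclear")
  expect_equal(classify_window(NA, 0.005, th), "unclear")
  # smaller divergence must be < 1.4%: both large => unclear
  expect_equal(classify_window(0.02, 0.03, th), "unclear")
  # but only the smaller one is bounded by default
  expect_equal(classify_window(0.005, 0.02, th), "sieversii")
  both <- classification_thresholds(both_bounded = TRUE)
  expect_equal(classify_window(0.005, 0.02, both), "unclear")
  # boundary equality is conservative
  expect_equal(classify_window(0.014, 0.017, th), "unclear")

  # species-swap symmetry on a random grid
  withr::with_seed(1, {
    a <- runif(200, 0, 0.03)
    b <- runif(200, 0, 0.03)
  })
  fwd <- classify_window(a, b, th)
  rev <- classify_window(b, a, th)
  swap <- c(sieversii = "sylvestris", sylvestris = "sieversii",
            unclear = "unclear")
  expect_identical(rev, unname(swap[fwd]))
})

make_windows <- function(calls_d, window = 1e4) {
  n <- nrow(calls_d)
  data.frame(chrom = "chr1", start = (0:(n - 1)) * window,
             end = (1:n) * window,
             aligned_sie = window, mismatch_sie = round(window * calls_d$p_sie),
             aligned_syl = window, mismatch_syl = round(window * calls_d$p_syl))
}

test_that("painting merges runs into tracts and locates recombination sites", {
  w <- make_windows(data.frame(p_sie = rep(0.006, 5), p_syl = rep(0.02, 5)))
  p <- paint_haplome(w, th)
  expect_equal(nrow(p$tracts), 1)
  expect_equal(p$tracts$origin, "sieversii")
  expect_equal(p$tracts$n_windows, 5)
  expect_equal(nrow(p$boundaries), 0)
  f <- origin_fractions(p)
  expect_equal(sum(f), 1)
  expect_equal(f[["sieversii"]], 1)

  # alternating origins: one tract per window
  alt <- make_windows(data.frame(p_sie = rep(c(0.006, 0.02), 5),
                                 p_syl = rep(c(0.02, 0.006), 5)))
  pa <- paint_haplome(alt, th)
  expect_equal(nrow(pa$tracts), 10)
  expect_equal(nrow(pa$boundaries), 9)

  # an unclear gap between two origins: boundary spans the gap
  gap <- make_windows(data.frame(p_sie = c(0.006, 0.012, 0.02),
                                 p_syl = c(0.02, 0.012, 0.006)))
  pg <- paint_haplome(gap, th)
  expect_equal(nrow(pg$boundaries), 1)
  expect_equal(pg$boundaries$start, 1e4)
  expect_equal(pg$boundaries$end, 2e4)
})

test_that("diploid summary classifies hybrid, homozygous and unresolved windows", {
  wA <- make_windows(data.frame(p_sie = rep(0.006, 4), p_syl = rep(0.02, 4)))
  wB <- make_windows(data.frame(p_sie = rep(0.02, 4), p_syl = rep(0.006, 4)))
  s <- summarize_painting(paint_haplome(wA, th), paint_haplome(wB, th))
  expect_equal(s$diploid[["hybrid"]], 1)
  expect_equal(sum(s$diploid), 1)

  s2 <- summarize_painting(paint_haplome(wA, th), paint_haplome(wA, th))
  expect_equal(s2$diploid[["hybrid"]], 0)
  expect_equal(s2$diploid[["homo_sie"]], 1)

  wOther <- make_windows(data.frame(p_sie = rep(0.006, 3), p_syl = rep(0.02, 3)))
  expect_error(summarize_painting(paint_haplome(wA, th),
                                  paint_haplome(wOther, th)), "grid")
})

test_that("mosaic painting recovers planted window origins", {
  cfg <- simulation_config(genome_length = 5e6, tract_length_mean = 5e5,
                           window_size = 5e4, seed = 7)
  pg <- simulate_progenitor_pair(simulation_config(genome_length = 1e4, seed = 7))
  hy <- simulate_hybrid_diploid(pg, cfg)
  obs <- simulate_window_observations(hy$truth, cfg)
  acc <- c()
  for (h in c("A", "B")) {
    oh <- obs[obs$haplome == h, ]
    p <- paint_haplome(oh, th)
    truth_h <- hy$truth[hy$truth$haplome == h, ]
    true_origin <- vapply(seq_len(nrow(p$windows)), function(i) {
      ov <- pmin(truth_h$end, p$windows$end[i]) -
        pmax(truth_h$start, p$windows$start[i])
      truth_h$origin[which.max(ifelse(ov > 0, ov, 0))]
    }, "")
    cl <- p$windows$call != "unclear"
    acc <- c(acc, mean(p$windows$call[cl] == true_origin[cl]))
  }
  expect_true(all(acc >= 0.95))
})

test_that("sensitivity scan degenerates correctly and reports spread", {
  cfg <- simulation_config(genome_length = 1e6, tract_length_mean = 2e5,
                           window_size = 2.5e4, seed = 13)
  hy <- simulate_hybrid_diploid(simulate_progenitor_pair(
    simulation_config(genome_length = 1e4, seed = 13)), cfg)
  blocks <- simulate_alignment_blocks(hy$truth, cfg, haplome = "A",
                                      block_size = 1000)
  one <- sensitivity_scan(blocks, window_sizes = 5e4, min_aligned_list = 100,
                          chrom_lengths = c(chr1 = 1e6))
  w <- project_to_windows(blocks, 5e4, 100, chrom_lengths = c(chr1 = 1e6))
  f <- origin_fractions(paint_haplome(w, th))
  expect_equal(one$fraction_sieversii, f[["sieversii"]])
  expect_equal(one$fraction_sylvestris, f[["sylvestris"]])

  # window larger than the chromosome: a single window
  big <- project_to_windows(blocks, 2e6, 100, chrom_lengths = c(chr1 = 1e6))
  expect_equal(nrow(big), 1)
})

test_that("regions inherit the plurality origin of overlapping tracts", {
  tracts <- data.frame(chrom = "chr1",
                       start = c(0, 1e5, 2e5),
                       end = c(1e5, 2e5, 3e5),
                       origin = c("sieversii", "sylvestris", "unclear"))
  reg <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2"),
                    start = c(10, 0.4e5, 2.1e5, 0),
                    end = c(1000, 1.5e5, 2.9e5, 100))
  expect_warning(out <- intersect_regions_with_ancestry(reg, tracts),
                 "unknown")
  expect_equal(out$origin, c("sieversii", "sieversii", "unclear"))
  # 60/40 split across two origins takes the majority side
  reg2 <- data.frame(chrom = "chr1", start = 0.4e5, end = 1.4e5)
  expect_equal(intersect_regions_with_ancestry(reg2, tracts)$origin,
               "sieversii")
  reg3 <- data.frame(chrom = "chr1", start = 0.6e5, end = 1.6e5)
  expect_equal(intersect_regions_with_ancestry(reg3, tracts)$origin,
               "sylvestris")
  # exact tie is unclear
  expect_equal(intersect_regions_with_ancestry(
    data.frame(chrom = "chr1", start = 0, end = 2e5), tracts)$origin,
    "unclear")
})
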