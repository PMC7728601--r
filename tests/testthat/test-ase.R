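test_that("read assignment follows the one-strict score/mismatch rule", {
  ev <- data.frame(
    score_A = c(60, 55, 60, 60, 60, 60),
    score_B = c(55, 60, 60, 60, 60, 55),
    mm_A =    c(0,  1,  0,  1,  1,  0),
    mm_B =    c(1,  0,  1,  0,  1,  1),
    uniquely_aligned_both = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    same_chromosome = TRUE
  )
  out <- assign_read(ev)
  # equal scores with fewer mismatches is enough by default...
  expect_equal(out, c("A", "B", "A", "B", "ambiguous", "ambiguous"))
  # ...but not under strict_both
  strict <- assign_read(ev, strict_both = TRUE)
  expect_equal(strict[3:4], c("ambiguous", "ambiguous"))
  expect_equal(strict[1:2], c("A", "B"))
})

test_that("read assignment is equivariant under allele relabeling", {
  withr::with_seed(2, {
    ev <- data.frame(score_A = sample(50:62, 100, TRUE),
                     score_B = sample(50:62, 100, TRUE),
                     mm_A = sample(0:3, 100, TRUE),
                     mm_B = sample(0:3, 100, TRUE))
  })
  fwd <- assign_read(ev)
  swapped <- assign_read(data.frame(score_A = ev$score_B, score_B = ev$score_A,
                                    mm_A = ev$mm_B, mm_B = ev$mm_A))
  map <- c(A = "B", B = "A", ambiguous = "ambiguous")
  expect_identical(swapped, unname(map[fwd]))
  # every read lands in exactly one class
  expect_true(all(fwd %in% c("A", "B", "ambiguous")))
})

test_that("phasing imputes the complementary allele and drops contradictions", {
  v <- data.frame(chrom = "chr1", pos = 1:5, ref = "C", alt = "A",
                  hap_A = c("C", NA, "C", "C", "G"),
                  hap_B = c(NA, "A", "A", "C", "A"))
  ph <- phase_and_impute(v)
  # only-one-side-known sites are imputed with the remaining allele
  expect_equal(ph$source[ph$pos %in% 1:2], c("imputed", "imputed"))
  expect_equal(ph$allele_B[ph$pos == 1], "A")
  expect_equal(ph$allele_A[ph$pos == 2], "C")
  expect_equal(ph$source[ph$pos == 3], "direct")
  # same base on both haplomes, or off-call bases: dropped
  expect_false(any(c(4, 5) %in% ph$pos))
})

test_that("SNP-split voting assigns by majority and skips foreign bases", {
  phased <- data.frame(chrom = "chr1", pos = c(100, 200, 300),
                       allele_A = c("C", "G", "T"),
                       allele_B = c("A", "T", "C"), source = "direct")
  ro <- data.frame(
    read_id = c("r1", "r1", "r2", "r2", "r3", "r4"),
    chrom = "chr1",
    pos = c(100, 200, 100, 200, 300, 100),
    base = c("C", "G", "C", "T", "G", "A")
  )
  out <- snp_split_read(ro, phased)
  expect_equal(out$assignment[out$read_id == "r1"], "A")  # 2 votes A
  expect_equal(out$assignment[out$read_id == "r2"], "ambiguous")  # tie
  expect_equal(out$assignment[out$read_id == "r3"], "ambiguous")  # no vote
  expect_equal(out$assignment[out$read_id == "r4"], "B")
})

test_that("assignment balance is near one for symmetric counts", {
  sim <- simulate_ase_counts(300, stages = 4, seed = 17)
  bal <- assignment_balance(sim$counts)
  expect_gt(bal$overall, 0.95)
  expect_lt(bal$overall, 1.05)
  expect_equal(nrow(bal$per_stage), 4)
  lop <- data.frame(stage = 1, count_A = c(10, 20), count_B = c(0, 0))
  expect_warning(b2 <- assignment_balance(lop), "infinite")
  expect_true(is.infinite(b2$overall))
})

test_that("ASE test calls planted imbalance, not balanced genes", {
  eff <- matrix(0, 60, 2)
  eff[1:15, ] <- 2  # 4-fold genes
  sim <- simulate_ase_counts(60, stages = 2, effect_spec = eff,
                             mean_depth = 300, seed = 23)
  calls <- ase_test(sim$counts)
  planted <- calls$gene %in% paste0("g", 1:15)
  expect_gt(mean(calls$significant[planted]), 0.85)
  expect_lt(mean(calls$significant[!planted]), 0.1)
  expect_true(all(calls$dominant_allele[calls$significant &
                                          calls$log2_ratio > 0] == "A"))

  # identical allele counts: zero ratio, not significant
  ident <- data.frame(gene = "g", stage = 1, rep = 1:3,
                      count_A = c(50, 60, 70), count_B = c(50, 60, 70))
  ic <- ase_test(ident)
  expect_equal(ic$log2_ratio, 0)
  expect_false(ic$significant)
})

test_that("ASE calls are antisymmetric under allele swap", {
  sim <- simulate_ase_counts(40, stages = 3, seed = 31,
                             effect_spec = matrix(rnorm(120), 40, 3))
  fwd <- ase_test(sim$counts)
  sw <- sim$counts
  tmp <- sw$count_A; sw$count_A <- sw$count_B; sw$count_B <- tmp
  rev <- ase_test(sw)
  expect_equal(rev$log2_ratio, -fwd$log2_ratio)
  expect_equal(rev$p, fwd$p)
  expect_equal(rev$padj, fwd$padj)
  expect_identical(rev$significant, fwd$significant)
})

test_that("low-count replicates exclude a gene-stage; single reps fall back", {
  counts <- data.frame(
    gene = rep(c("g1", "g2"), each = 3), stage = 1, rep = 1:3,
    count_A = c(100, 100, 4, 100, 100, 100),
    count_B = c(90, 90, 5, 90, 90, 90)
  )
  out <- ase_test(counts)   # g1 has a replicate with total 9 <= 10
  expect_equal(out$gene, "g2")
  single <- data.frame(gene = "g1", stage = 1, rep = 1,
                       count_A = 90, count_B = 10)
  expect_warning(s <- ase_test(single), "binomial")
  expect_equal(s$p, binom.test(90, 100, 0.5)$p.value)
})

test_that("dominance profiling distinguishes consistent, switching, single-stage", {
  calls <- data.frame(
    gene = rep(c("gA", "gSw", "g1", "gNo"), each = 3),
    stage = rep(1:3, 4), n_reps = 3, mean_A = 10, mean_B = 10,
    log2_ratio = c(2, 2, 2, 2, -2, 0, 2, 0, 0, 0, 0, 0),
    p = 0.001, padj = c(rep(0.001, 5), 0.9, 0.001, 0.9, 0.9, 0.9, 0.9, 0.9)
  )
  calls$significant <- calls$padj < 0.05 & abs(calls$log2_ratio) > 1
  calls$dominant_allele <- ifelse(!calls$significant, "none",
                                  ifelse(calls$log2_ratio > 0, "A", "B"))
  prof <- dominance_profile(calls)
  expect_equal(prof$class[prof$gene == "gA"], "consistent_A")
  expect_equal(prof$class[prof$gene == "gSw"], "switching")
  expect_equal(prof$class[prof$gene == "g1"], "single_stage")
  expect_equal(prof$class[prof$gene == "gNo"], "none")
})

test_that("hybrid-ancestry enrichment recovers planted odds ratios", {
  withr::with_seed(41, {
    n <- 8000
    hybrid <- runif(n) < 0.3
    # planted ~2x odds of ASE for hybrid-ancestry genes
    p_ase <- ifelse(hybrid, 0.30, 0.176)   # OR = (0.3/0.7)/(0.176/0.824) ~ 2
    ase <- runif(n) < p_ase
  })
  res <- ancestry_enrichment_test(hybrid, ase)
  expect_gt(res$odds_ratio, 1.8)
  expect_lt(res$odds_ratio, 2.2)
  expect_lt(res$p, 1e-10)
  expect_error(ancestry_enrichment_test(rep(TRUE, 10), rep(c(TRUE, FALSE), 5)),
               "degenerate")
})

test_that("enrichment p-values are calibrated under independence", {
  withr::with_seed(43, {
    ps <- replicate(200, {
      hybrid <- runif(400) < 0.3
      ase <- runif(400) < 0.2
      ancestry_enrichment_test(hybrid, ase)$p
    })
  })
  expect_gt(min(ps), 0)
  expect_lt(mean(ps < 0.05), 0.09)  # near-nominal type-I error
  d <- suppressWarnings(ks.test(ps, "punif")$statistic)
  expect_lt(d, 0.12)
})

test_that("SV proximity test matches the exact permutation oracle", {
  withr::with_seed(47, {
    for (i in 1:10) {
      x <- sample(1000, 3)
      y <- setdiff(sample(1000, 6), x)[1:3]
      res <- sv_proximity_test(c(x, y), rep(c(TRUE, FALSE), each = 3))
      expect_equal(res$p, oracle_mw_p(x, y), tolerance = 1e-12)
    }
  })
  expect_equal(sv_proximity_test(rep(5, 10), rep(c(TRUE, FALSE), 5))$p, 1)
  # stochastically smaller ASE distances give small p
  withr::with_seed(48, {
    dist <- c(rexp(200, 1 / 1000), rexp(200, 1 / 4000))
  })
  res <- sv_proximity_test(dist, rep(c(TRUE, FALSE), each = 200))
  expect_lt(res$p, 1e-6)
  expect_error(sv_proximity_test(c(-1, 2), c(TRUE, FALSE)), "non-negative")
})
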