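test_that("hard filter applies exclusion rules with inclusive boundaries", {
  rec <- data.frame(
    QD = c(1.5, 2.0, 5, 5, 5),
    QUAL = c(80, 60, 59, 80, 80),
    SOR = c(1, 3, 1, 1, 1),
    FS = c(10, 60, 10, 10, 10),
    MQ = c(50, 40, 50, 50, 50),
    MQRankSum = c(0, -12.5, 0, 0, 0),
    ReadPosRankSum = c(0, -8, 0, 0, 0),
    ref_depth = c(20, 5, 20, 5, 20),
    alt_depth = c(20, 5, 20, 5, 4)
  )
  out <- hard_filter_variant(rec)
  expect_equal(out, c("fail(QD)", "pass", "fail(QUAL)", "pass",
                      "fail(allele_support)"))
  # missing annotations never fail their condition
  expect_equal(hard_filter_variant(data.frame(QUAL = 80)), "pass")
})

test_that("population filter enforces MAF, QUAL and missingness and is idempotent", {
  g <- rbind(
    rep(c(0, NA), c(1, 19)),          # 95% missing
    rep(c(0, 1), c(18, 2)),           # MAF = 2/40 = 0.05 exactly: retained
    rep(0, 20),                       # monomorphic
    rep(c(0, 2), c(10, 10))           # common variant
  )
  gm <- genotype_matrix(g, rep("pop", 20), qual = c(60, 60, 60, 25))
  f <- population_filter(gm)
  expect_equal(nrow(f$genotypes), 1)
  expect_equal(f$positions, 2)
  expect_identical(population_filter(f)$genotypes, f$genotypes)
})

test_that("allele frequencies and genotype classes match locus case studies", {
  # fruit-acidity locus style fixtures (Ma1-like SNP)
  syl <- simulate_genotype_matrix(
    data.frame(population = "sylvestris", hom_ref = 10, het = 1, hom_alt = 0))
  sie <- simulate_genotype_matrix(
    data.frame(population = "sieversii", hom_ref = 16, het = 16, hom_alt = 4))
  dom <- simulate_genotype_matrix(
    data.frame(population = "domestica", hom_ref = 4, het = 24, hom_alt = 8))
  expect_equal(allele_frequency(syl, "sylvestris"), 4.5)
  expect_equal(allele_frequency(sie, "sieversii"), 33.3)
  expect_equal(allele_frequency(dom, "domestica"), 55.6)
  expect_equal(genotype_class_proportions(dom, "domestica")[["het"]], 66.7)
  expect_equal(genotype_class_proportions(sie, "sieversii")[["het"]], 44.4)
  expect_equal(genotype_class_proportions(syl, "sylvestris")[["het"]], 9.1)

  all_alt <- genotype_matrix(matrix(2, 1, 6), rep("p", 6))
  expect_equal(allele_frequency(all_alt, "p"), 100)
  expect_equal(genotype_class_proportions(all_alt, "p"),
               c(hom_ref = 0, het = 0, hom_alt = 100))
})

test_that("frequency equals hom_alt + het/2 and is sample-order invariant", {
  withr::with_seed(4, {
    for (i in 1:10) {
      gm <- random_genotypes(1, 20)
      f <- allele_frequency(gm, site = 1, digits = NULL)
      cls <- genotype_class_proportions(gm, site = 1, digits = NULL)
      expect_equal(f, cls[["hom_alt"]] + cls[["het"]] / 2)
      perm <- sample.int(20)
      gm2 <- genotype_matrix(gm$genotypes[, perm, drop = FALSE],
                             gm$populations[perm])
      expect_equal(allele_frequency(gm2, site = 1, digits = NULL), f)
    }
  })
})

test_that("windowed pi matches explicit pairwise enumeration", {
  # 4 haplotypes, one site split 2/2: pi = 2/3 at the site
  gm <- genotype_matrix(matrix(c(1, 1), 1, 2), rep("p", 2), positions = 10)
  w <- nucleotide_diversity_windows(gm, window = 100, step = 100,
                                    length_bp = 100)
  expect_equal(w$pi[1], (2 / 3) / 100)
  expect_equal(oracle_site_pi(c(1, 1)), 2 / 3)

  # no segregating sites
  gm0 <- genotype_matrix(matrix(0, 3, 4), rep("p", 4), positions = c(1, 5, 9))
  expect_equal(nucleotide_diversity_windows(gm0, 10, 10, 10)$pi, 0)
})

test_that("Tajima's D is negative under an excess of rare variants", {
  # 30 samples, every site a singleton heterozygote
  n <- 30
  g <- matrix(0, 12, n)
  for (i in 1:12) g[i, (i %% n) + 1] <- 1
  gm <- genotype_matrix(g, rep("p", n), positions = seq(10, 120, by = 10))
  d <- tajimas_d_windows(gm, window = 200, step = 200, length_bp = 200)
  expect_lt(d$tajima_d[1], 0)
  expect_equal(d$tajima_d[1], oracle_tajima_d(g), tolerance = 1e-12)
  # windows with too few segregating sites are undefined, not dropped
  sparse <- genotype_matrix(g[1:2, ], rep("p", n), positions = c(10, 20))
  ds <- tajimas_d_windows(sparse, window = 200, step = 200, length_bp = 200)
  expect_true(is.na(ds$tajima_d[1]))
})

test_that("p-distance handles identity, opposition and missing data", {
  g <- matrix(c(0, 0, 2, 1,
                0, 0, 2, 1,
                2, 2, 0, NA), nrow = 3, byrow = TRUE)
  gm <- genotype_matrix(g, rep("p", 4))
  d <- p_distance_matrix(gm)
  expect_equal(d[1, 2], 0)                      # identical samples
  expect_equal(d[1, 3], 1)                      # opposite homozygotes
  # hand computation: s1 vs s4 over sites 1,2 (site 3 missing in s4)
  expect_equal(d[1, 4], mean(c(abs(0 - 1) / 2, abs(0 - 1) / 2)))
  expect_true(isSymmetric(d))
  expect_equal(diag(d), setNames(rep(0, 4), paste0("s", 1:4)))
})

test_that("neighbor joining inverts additive matrices exactly", {
  withr::with_seed(11, {
    for (i in 1:5) {
      at <- random_additive_tree(6)
      tr <- neighbor_joining(at$d)
      expect_equal(max(abs(cophenetic(tr)[rownames(at$d), colnames(at$d)] -
                             at$d)), 0, tolerance = 1e-9)
      expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), at$tree)), 0)
    }
  })
})

test_that("3-taxon NJ uses the closed form and labels are interchangeable", {
  d3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  tr <- neighbor_joining(d3)
  expect_equal(sort(tr$edge.length), c(0.5, 1.5, 2.5))
  # permuting taxa yields an isomorphic tree
  at <- withr::with_seed(5, random_additive_tree(7))
  perm <- withr::with_seed(6, sample.int(7))
  tr1 <- neighbor_joining(at$d)
  tr2 <- neighbor_joining(at$d[perm, perm])
  expect_equal(as.numeric(ape::dist.topo(tr1, tr2)), 0)
  expect_error(neighbor_joining(matrix(c(0, NA, NA, 0), 2, 2)), "3 taxa")
  dn <- at$d; dn[1, 2] <- dn[2, 1] <- NA
  expect_error(neighbor_joining(dn), "finite")
})

test_that("a minimal VCF parses into genotypes and filterable annotations", {
  path <- system.file("extdata", "acidity_locus_synthetic.vcf",
                      package = "malus")
  gm <- read_genotype_vcf(path, populations = rep("domestica", 6))
  expect_equal(dim(gm$genotypes), c(3L, 6L))
  expect_equal(gm$positions, c(1455, 2001, 3200))
  expect_true(is.na(gm$genotypes[2, 4]))
  expect_equal(allele_frequency(gm, "domestica", site = 1, digits = 1),
               round_half_away(100 * 5 / 12, 1))
  ann <- attr(gm, "annotations")
  # site 2 fails QD < 2 and QUAL < 60; site 3 fails SOR > 3
  expect_equal(hard_filter_variant(ann),
               c("pass", "fail(QD)", "fail(SOR)"))
})

test_that("VCF round trip preserves genotypes, positions and QUAL", {
  gm <- simulate_genotype_matrix(
    data.frame(population = "p", n = 8, freq = 0.4), mode = "hw",
    n_sites = 5, seed = 3)
  gm$genotypes[2, 1] <- NA
  path <- tempfile(fileext = ".vcf")
  write_genotype_vcf(gm, path)
  back <- read_genotype_vcf(path, populations = gm$populations)
  expect_equal(unname(back$genotypes), unname(gm$genotypes))
  expect_equal(back$positions, gm$positions)
  expect_equal(back$qual, gm$qual)
})
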