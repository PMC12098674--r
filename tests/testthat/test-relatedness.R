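test_that("KING-robust kinship: duplicates give exactly 0.5 and hand-counted sites match", {
  # 5 sites: (Aa,Aa),(Aa,Aa),(AA,aa),(Aa,AA),(aa,aa); pad with common hets so
  # the cohort MAF filter keeps every site
  hap0 <- cbind(c(0L, 0L, 0L, 0L, 1L), c(0L, 0L, 1L, 0L, 1L))
  hap1 <- cbind(c(1L, 1L, 0L, 1L, 1L), c(1L, 1L, 1L, 0L, 1L))
  pad0 <- matrix(0L, 5, 8)
  pad1 <- matrix(1L, 5, 8)
  g <- make_geno(cbind(hap0, pad0), cbind(hap1, pad1))
  k <- king_robust(g, "S1", "S2")
  expect_equal(k$n_AaAa, 2L)
  expect_equal(k$n_AAaa, 1L)
  expect_equal(k$n_Aa_i, 3L)
  expect_equal(k$n_Aa_j, 2L)
  expect_equal(k$phi, 0)
  dup <- king_robust(g, "S1", "S1")
  expect_equal(dup$phi, 0.5)
})

test_that("king_matrix equals the pairwise estimator including missing-data handling", {
  set.seed(7)
  nv <- 400
  ns <- 6
  hap0 <- matrix(rbinom(nv * ns, 1, 0.4), nv, ns)
  hap1 <- matrix(rbinom(nv * ns, 1, 0.4), nv, ns)
  hap0[sample(length(hap0), 50)] <- NA
  g <- make_geno(hap0, hap1)
  km <- king_matrix(g)
  for (r in seq_len(nrow(km))) {
    k <- king_robust(g, km$sample1[r], km$sample2[r])
    expect_equal(km$phi[r], k$phi)
    expect_equal(km$n_sites[r], k$n_sites)
  }
})

test_that("IBD merging applies the gap and discordant-homozygote rules", {
  map <- linear_map() # 100 cM over 10 Mb: 0.5 cM = 50 kb
  seg <- function(gap_bp) validate_ibd(data.frame(
    sample1 = "S1", hap1 = 1L, sample2 = "S2", hap2 = 1L, chrom = "chr1",
    start = c(0L, 2000000L + gap_bp), end = c(2000000L, 4000000L),
    cM = c(20, (2000000L - gap_bp) / 1e5)))
  clean <- make_geno(matrix(0L, 3, 2), matrix(0L, 3, 2))
  # 0.5 cM gap, 0 discordant homozygotes -> merged
  m <- merge_ibd(seg(50000L), clean, map)
  expect_equal(nrow(m), 1L)
  expect_equal(m$cM, 40)
  # 0.7 cM gap -> not merged
  m2 <- merge_ibd(seg(70000L), clean, map)
  expect_equal(nrow(m2), 2L)
  # 0.5 cM gap with 2 opposite homozygotes inside -> not merged
  disc <- cohort_genotypes(
    c("S1", "S2"),
    data.frame(chrom = "chr1", pos = c(2010000L, 2020000L, 2030000L),
               ref = "A", alt = "G"),
    hap0 = cbind(c(0L, 0L, 0L), c(1L, 1L, 0L)),
    hap1 = cbind(c(0L, 0L, 0L), c(1L, 1L, 0L)))
  m3 <- merge_ibd(seg(50000L), disc, map)
  expect_equal(nrow(m3), 2L)
  # with exactly one discordant homozygote the merge goes through
  disc1 <- cohort_genotypes(
    c("S1", "S2"),
    data.frame(chrom = "chr1", pos = 2010000L, ref = "A", alt = "G"),
    hap0 = cbind(0L, 1L), hap1 = cbind(0L, 1L))
  expect_equal(nrow(merge_ibd(seg(50000L), disc1, map)), 1L)
})

test_that("IBD merging is idempotent and never decreases total IBD", {
  map <- linear_map()
  set.seed(17)
  for (i in 1:30) {
    n <- sample(2:8, 1)
    cuts <- sort(sample.int(10000000L, 2L * n))
    starts <- cuts[seq(1, 2L * n, 2)]
    ends <- cuts[seq(2, 2L * n, 2)]
    segs <- validate_ibd(data.frame(
      sample1 = "S1", hap1 = 1L, sample2 = "S2", hap2 = 2L, chrom = "chr1",
      start = starts, end = ends, cM = (ends - starts) / 1e5))
    m1 <- suppressWarnings(merge_ibd(segs, NULL, map))
    m2 <- suppressWarnings(merge_ibd(m1, NULL, map))
    expect_equal(m1, m2)
    expect_gte(sum(m1$cM), sum(segs$cM) - 1e-9)
  }
})

test_that("total IBD sums channels and chromosomes; degree bins follow the published cutpoints", {
  empty <- validate_ibd(data.frame(sample1 = character(), hap1 = integer(),
                                   sample2 = character(), hap2 = integer(),
                                   chrom = character(), start = integer(),
                                   end = integer(), cM = numeric()))
  expect_equal(nrow(total_ibd(empty)), 0L)
  two <- validate_ibd(data.frame(sample1 = "S1", hap1 = c(1L, 2L),
                                 sample2 = "S2", hap2 = 1L,
                                 chrom = c("chr1", "chr2"),
                                 start = 0L, end = 1000L, cM = c(10, 15)))
  expect_equal(total_ibd(two)$total_ibd_cM, 25)
  expect_equal(classify_degree(phi = c(0.25, 0.0884, 0.08841, 0.01, 0.4)),
               c("first", "third", "second", "unrelated", "duplicate"))
  expect_equal(classify_degree(total_ibd_cM = 1750, L_tot_cM = 3500), "second")
})

test_that("parent-offspring truth segments total the map length exactly; MZ doubles it", {
  cfg <- two_anc_config(seed = 1)
  set.seed(2)
  ped <- data.frame(id = c("P", "Q", "C"), father = c(NA, NA, "P"),
                    mother = c(NA, NA, "Q"))
  rel <- simulate_relatives(cfg, ped)
  ibd <- true_ibd_segments(rel$individuals$P, rel$individuals$C, "C", "P", cfg)
  expect_equal(sum(ibd$cM), 100)
  mz <- true_ibd_segments(rel$individuals$P, rel$individuals$P, "P", "P2", cfg)
  expect_equal(sum(mz$cM), 200)
})

test_that("race concordance: deterministic race labels give zero discordant related pairs", {
  md <- validate_metadata(data.frame(sample = c("A", "B", "C", "D"),
                                     race = c("Black", "Black", "White", "White"),
                                     zone = "Z1", age = 30))
  cats <- setNames(c("AFR", "AFR", "EUR", "EUR"), md$sample)
  # full sibs under the channel-sum convention share ~L_tot in total
  pairs <- data.frame(sample1 = c("A", "C"), sample2 = c("B", "D"),
                      total_ibd_cM = c(3400, 3600))
  rc <- race_concordance(pairs, md, cats, L_tot_cM = 3500)
  expect_equal(rc$summary$n_related_discordant_race, 0L)
  expect_equal(rc$summary$n_related, 2L)
  # sibs with different labels appear as first degree, different race
  md2 <- md
  md2$race <- c("Black", "White", "White", "White")
  md2 <- validate_metadata(md2)
  rc2 <- race_concordance(pairs[1, ], md2, cats, L_tot_cM = 3500)
  expect_equal(rc2$pairs$degree, "first")
  expect_false(rc2$pairs$same_race)
})

test_that("simulated pedigrees recover expected kinship by class", {
  cfg <- sim_config(labels = c("A", "B"), g = 1,
                    subcohorts = list(list(weight = 1, alpha = c(A = 1, B = 1))),
                    chrom = data.frame(chrom = paste0("chr", 1:10),
                                       bp = 1e7, cM = 100),
                    n_variants = 4000, n_samples = 0,
                    freq_model = list(functional = c(5, 5), modifier = c(5, 5),
                                      shared = TRUE, deleterious_ratio = NULL),
                    catalog_model = c(A = 0.9, B = 0.9), relatives = c())
  set.seed(31)
  ped <- data.frame(id = c("F", "M", "C", "U1", "U2"),
                    father = c(NA, NA, "F", NA, NA),
                    mother = c(NA, NA, "M", NA, NA))
  rel <- simulate_relatives(cfg, ped)
  vs <- simulate_variants(cfg)
  geno <- simulate_genotypes(rel, vs)
  expect_equal(king_robust(geno, "F", "C")$phi, 0.25, tolerance = 0.05)
  expect_lt(abs(king_robust(geno, "U1", "U2")$phi), 0.05)
})

test_that("cyclic pedigrees are rejected", {
  cfg <- two_anc_config()
  ped <- data.frame(id = c("A", "B"), father = c("B", "A"), mother = c("B", "A"))
  expect_error(simulate_relatives(cfg, ped), class = "admixcohort_validation")
})
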