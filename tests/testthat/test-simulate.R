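test_that("degenerate proportions give a single tract per chromosome", {
  cfg <- two_anc_config()
  set.seed(1)
  tr <- simulate_tracts(cfg, c(1, 0))
  expect_equal(nrow(tr), 2L) # one per haplotype, one chromosome
  expect_true(all(tr$anc == 0L))
  expect_true(all(tr$start == 0L & tr$end == 1e7))
})

test_that("tracts tile each chromosome exactly and carry valid codes", {
  cfg <- sim_config(labels = c("A", "B", "C"),
                    subcohorts = list(list(weight = 1,
                                           alpha = c(A = 2, B = 2, C = 2))),
                    chrom = data.frame(chrom = c("chr1", "chr2"),
                                       bp = c(5e6, 8e6), cM = c(50, 80)),
                    catalog_model = c(A = .9, B = .9, C = .9), relatives = c())
  set.seed(3)
  for (i in 1:10) {
    m <- as.vector(rdirichlet(1, c(2, 2, 2)))
    tr <- simulate_tracts(cfg, m)
    for (h in unique(tr$hap)) {
      for (ch in c("chr1", "chr2")) {
        t0 <- tr[tr$hap == h & tr$chrom == ch, ]
        expect_equal(t0$start[1], 0L)
        expect_equal(t0$end[nrow(t0)],
                     as.integer(cfg$chrom$bp[cfg$chrom$chrom == ch]))
        if (nrow(t0) > 1) {
          expect_equal(t0$start[-1], t0$end[-nrow(t0)])
          expect_true(all(diff(t0$anc) != 0L)) # merged adjacents
        }
      }
    }
    expect_true(all(tr$anc %in% 0:2))
  }
})

test_that("visible switch rate matches the thinned Poisson expectation", {
  cfg <- sim_config(labels = c("A", "B"),
                    subcohorts = list(list(weight = 1, alpha = c(A = 1, B = 1))),
                    chrom = data.frame(chrom = "chr1", bp = 1e7, cM = 100),
                    g = 12, catalog_model = c(A = .9, B = .9), relatives = c())
  set.seed(8)
  n_hap <- 500
  tr <- simulate_tracts(cfg, c(0.5, 0.5), n_hap = n_hap)
  switches <- tabulate(tr$hap, n_hap) - 1L
  expected <- 12 * 1 * (1 - 0.5^2 - 0.5^2) # 6 visible switches
  se <- stats::sd(switches) / sqrt(n_hap)
  expect_lt(abs(mean(switches) - expected), 3 * se)
})

test_that("bp-weighted ancestry fraction recovers the proportion vector", {
  cfg <- two_anc_config()
  set.seed(9)
  n_hap <- 500
  tr <- simulate_tracts(cfg, c(0.3, 0.7), n_hap = n_hap)
  frac <- vapply(split(tr, tr$hap), function(t0) {
    sum((t0$end - t0$start)[t0$anc == 0L]) / 1e7
  }, 0)
  se <- stats::sd(frac) / sqrt(n_hap)
  expect_lt(abs(mean(frac) - 0.3), 3 * se)
})

test_that("degenerate frequencies make alleles follow tract ancestry exactly", {
  cfg <- two_anc_config(seed = 12)
  set.seed(12)
  ped <- data.frame(id = c("U1", "U2", "U3"), father = NA_character_,
                    mother = NA_character_)
  rel <- simulate_relatives(cfg, ped)
  nv <- 200
  vars <- data.frame(chrom = "chr1", pos = sort(sample.int(1e7, nv)),
                     ref = "A", alt = "G")
  vs <- list(variants = vars,
             freqs = matrix(c(1, 0), nv, 2, byrow = TRUE,
                            dimnames = list(NULL, c("A", "B"))))
  geno <- simulate_genotypes(rel, vs)
  for (s in geno$samples) {
    hap_id <- rel$hap_ids[s, 1]
    anc <- tract_anc_at(rel$founder_tracts[[as.character(hap_id)]],
                        vars$chrom, vars$pos)
    expect_equal(unname(geno$hap0[, s]), as.integer(anc == 0L))
  }
})

test_that("cohort AF collapses to f when every ancestry has the same frequency", {
  cfg <- sim_config(labels = c("A", "B"),
                    subcohorts = list(list(weight = 1, alpha = c(A = 2, B = 2))),
                    chrom = data.frame(chrom = "chr1", bp = 1e7, cM = 100),
                    n_samples = 150, n_variants = 60,
                    freq_model = list(functional = c(1e6, 1e6),
                                      modifier = c(1e6, 1e6),
                                      deleterious_ratio = NULL),
                    catalog_model = c(A = .9, B = .9), relatives = c(), seed = 14)
  sim <- simulate_cohort(cfg)
  af <- cohort_af(sim$geno)
  # Beta(1e6, 1e6) pins every frequency at 0.5
  n_al <- 2 * length(sim$geno$samples)
  se <- sqrt(0.5 * 0.5 / n_al)
  expect_true(all(abs(af - 0.5) < 4 * se + 3 * se)) # generous envelope
  expect_lt(abs(mean(af) - 0.5), 3 * se / sqrt(length(af)))
})

test_that("ancestry-biased catalog completeness raises novel counts in the underrepresented group", {
  cfg <- sim_config(labels = c("A", "B"),
                    subcohorts = list(
                      list(weight = 0.5, alpha = c(A = 30, B = 1)),
                      list(weight = 0.5, alpha = c(A = 1, B = 30))),
                    chrom = data.frame(chrom = "chr1", bp = 1e7, cM = 100),
                    n_samples = 120, n_variants = 2000,
                    catalog_model = c(A = 0.99, B = 0.80),
                    relatives = c(), seed = 15)
  sim <- simulate_cohort(cfg)
  flags <- variant_flags(sim$geno, sim$annotations)
  nv <- novelty_by_group(sim$geno, flags, sim$truth$categories)
  mean_by <- tapply(nv$n_novel, nv$group, mean)
  expect_gt(mean_by[["B"]], mean_by[["A"]])
})

test_that("monozygotic duplicates have identical genotypes; emitted msp equals truth tracts", {
  cfg <- two_anc_config(n_samples = 4, n_variants = 150, seed = 16)
  cfg$relatives <- c(mz = 1L)
  sim <- simulate_cohort(cfg)
  pr <- sim$truth$pairs
  mzp <- pr[pr$type == "mz", ]
  expect_equal(sim$geno$hap0[, mzp$id1], sim$geno$hap0[, mzp$id2],
               ignore_attr = TRUE)
  expect_equal(sim$geno$hap1[, mzp$id1], sim$geno$hap1[, mzp$id2],
               ignore_attr = TRUE)
  # every msp window call equals the truth tract ancestry at that window
  w <- sim$calls$windows
  for (s in sim$geno$samples[1:3]) {
    for (h in 0:1) {
      tr <- sim$truth$tracts[sim$truth$tracts$sample == s &
                               sim$truth$tracts$hap == h, ]
      want <- tract_anc_at(tr, w$chrom, w$spos + 1L)
      expect_equal(unname(sim$calls$calls[, paste0(s, ".", h)]), want)
    }
  }
})

test_that("full-sib truth IBD kinship averages 0.25", {
  cfg <- sim_config(labels = c("A", "B"), g = 2,
                    subcohorts = list(list(weight = 1, alpha = c(A = 1, B = 1))),
                    chrom = data.frame(chrom = paste0("chr", 1:6),
                                       bp = 1e7, cM = 100),
                    catalog_model = c(A = .9, B = .9), relatives = c())
  set.seed(18)
  n_rep <- 60
  phis <- replicate(n_rep, {
    ped <- data.frame(id = c("F", "M", "C1", "C2"),
                      father = c(NA, NA, "F", "F"),
                      mother = c(NA, NA, "M", "M"))
    rel <- simulate_relatives(cfg, ped)
    ibd <- true_ibd_segments(rel$individuals$C1, rel$individuals$C2,
                             "C1", "C2", cfg)
    sum(ibd$cM) / (4 * 600)
  })
  se <- stats::sd(phis) / sqrt(n_rep)
  expect_lt(abs(mean(phis) - 0.25), 3 * se)
})

test_that("identity race confusion makes race deterministic; segregated zones give D = 1", {
  cfg <- two_anc_config(n_samples = 40, n_variants = 100, seed = 19)
  cfg$race_discordance <- 0
  conf <- race_confusion_matrix(c("A", "B"), cfg)
  expect_true(all(rowSums(conf) == 1))
  expect_true(all(apply(conf, 1, max) == 1))
  # fully segregated zone weights
  cfg$zone_model <- list(weights = matrix(c(1, 0, 0, 1), 2, 2,
                                          dimnames = list(NULL, c("A", "B"))))
  sim <- simulate_cohort(cfg)
  md <- sim$metadata
  cats <- sim$truth$categories
  dom <- ifelse(sim$truth$proportions[, "A"] >= 0.5, "A", "B")
  ca <- table(md$zone[dom[md$sample] == "A"])
  cb <- table(md$zone[dom[md$sample] == "B"])
  if (length(ca) && length(cb)) {
    expect_equal(dissimilarity_index(ca, cb, geo_params(min_zone_n = 1)), 1)
  }
})

test_that("the same seed reproduces emitted files byte-for-byte", {
  cfg <- two_anc_config(n_samples = 10, n_variants = 120, seed = 77)
  d1 <- file.path(tempdir(), "simA")
  d2 <- file.path(tempdir(), "simB")
  write_cohort(simulate_cohort(cfg), d1)
  write_cohort(simulate_cohort(cfg), d2)
  for (f in c("cohort.vcf", "local_ancestry.msp.tsv", "genetic_map.tsv",
              "annotations.tsv", "metadata.tsv", "ibd_truth.tsv",
              file.path("truth", "tracts.tsv"))) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})
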