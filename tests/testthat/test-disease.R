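test_that("Wald prevalence interval matches the closed form and truncates", {
  p0 <- prevalence_ci(0, 50)
  expect_equal(c(p0$p_hat, p0$ci_low, p0$ci_high), c(0, 0, 0))
  p1 <- prevalence_ci(50, 50)
  expect_equal(c(p1$p_hat, p1$ci_low, p1$ci_high), c(1, 1, 1))
  p <- prevalence_ci(128, 1000)
  expect_equal(p$p_hat, 0.128)
  expect_equal(p$ci_low, 0.128 - 1.959964 * sqrt(0.128 * 0.872 / 1000),
               tolerance = 1e-6)
  expect_equal(round(c(p$ci_low, p$ci_high), 4), c(0.1073, 0.1487))
  expect_error(prevalence_ci(1, 0), class = "admixcohort_validation")
})

test_that("Wald interval width shrinks as 1/sqrt(n)", {
  widths <- vapply(c(250, 1000, 4000), function(n) {
    p <- prevalence_ci(round(0.1 * n), n)
    p$ci_high - p$ci_low
  }, 0)
  expect_equal(widths[1] / widths[2], 2, tolerance = 0.01)
  expect_equal(widths[2] / widths[3], 2, tolerance = 0.01)
})

test_that("odds ratio: point estimate, Woolf interval, zero-cell correction, symmetries", {
  o <- odds_ratio(table2x2(10, 10, 10, 10))
  expect_equal(o$or, 1)
  expect_equal(o$ci_low * o$ci_high, 1, tolerance = 1e-12)
  o2 <- odds_ratio(table2x2(10, 20, 30, 40))
  expect_equal(o2$or, 2 / 3, tolerance = 1e-12)
  expect_equal(c(o2$ci_low, o2$ci_high),
               exp(log(2 / 3) + c(-1, 1) * stats::qnorm(0.975) *
                     sqrt(1 / 10 + 1 / 20 + 1 / 30 + 1 / 40)),
               tolerance = 1e-12)
  expect_equal(c(o2$ci_low, o2$ci_high), c(0.2725, 1.6310), tolerance = 2e-4)
  oz <- odds_ratio(table2x2(0, 10, 10, 10))
  expect_true(oz$corrected)
  expect_equal(oz$or, (0.5 * 10.5) / (10.5 * 10.5))
  # swap (a,b,c,d) -> (d,c,b,a) leaves OR unchanged; flipping exposure inverts
  o3 <- odds_ratio(table2x2(40, 30, 20, 10))
  expect_equal(o3$or, o2$or)
  o4 <- odds_ratio(table2x2(30, 40, 10, 20))
  expect_equal(o4$or, 1 / o2$or)
  # Woolf interval equals a logistic-fit Wald interval
  fit <- stats::glm(cbind(c(10, 30), c(20, 40)) ~ c(1, 0), family = stats::binomial(),
                      control = stats::glm.control(epsilon = 1e-14, maxit = 100))
  expect_equal(log(o2$or), unname(stats::coef(fit)[2]), tolerance = 1e-6)
  expect_equal(o2$log_se, unname(sqrt(diag(stats::vcov(fit)))[2]), tolerance = 1e-6)
})

test_that("Mantel-Haenszel pools correctly and matches the crude OR for one stratum", {
  t1 <- table2x2(12, 5, 7, 9)
  mh1 <- mantel_haenszel(list(t1))
  expect_equal(mh1$or, odds_ratio(t1)$or)
  # identical strata with OR 1 pool to 1
  tt <- table2x2(10, 10, 10, 10)
  expect_equal(mantel_haenszel(list(tt, tt, tt))$or, 1)
  # strata with an empty margin are dropped and counted
  t_bad <- table2x2(0, 0, 5, 5)
  mh <- mantel_haenszel(list(t1, t_bad))
  expect_equal(mh$dropped, 1L)
  expect_equal(mh$k, 1L)
})

test_that("Mantel-Haenszel point estimate and RBG variance match independent references", {
  skip_if_not_installed("metafor")
  set.seed(55)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    tabs <- lapply(seq_len(k), function(j) {
      table2x2(sample(3:60, 1), sample(3:60, 1), sample(3:60, 1), sample(3:60, 1))
    })
    mh <- mantel_haenszel(tabs)
    m <- do.call(rbind, lapply(tabs, function(t) c(t$a, t$b, t$c, t$d)))
    fit <- metafor::rma.mh(ai = m[, 1], bi = m[, 2], ci = m[, 3], di = m[, 4],
                           measure = "OR", correct = FALSE)
    expect_equal(mh$log_or, as.numeric(fit$beta), tolerance = 1e-10)
    expect_equal(mh$log_se, fit$se, tolerance = 1e-10)
    st <- array(0, dim = c(2, 2, k))
    for (j in seq_len(k)) st[, , j] <- matrix(m[j, c(1, 3, 2, 4)], 2)
    expect_equal(mh$or, unname(stats::mantelhaen.test(st)$estimate),
                 tolerance = 1e-10)
  }
})

test_that("reference panel comparison is deterministic in the seed and validates the pool", {
  set.seed(60)
  n <- 400
  race <- sample(c("White", "Black"), n, replace = TRUE)
  md <- data.frame(sample = paste0("S", 1:n), race = race, zone = "Z1", age = 30)
  for (j in 1:25) {
    md[[paste0("c", j)]] <- sample(c("case", "control"), n, replace = TRUE,
                                   prob = c(0.2, 0.8))
  }
  md$target <- sample(c("case", "control"), n, replace = TRUE, prob = c(0.3, 0.7))
  md <- validate_metadata(md)
  r1 <- reference_panel_or(md, "target", n_ref = 20, min_cases = 5, seed = 9)
  r2 <- reference_panel_or(md, "target", n_ref = 20, min_cases = 5, seed = 9)
  expect_identical(r1$reference_conditions, r2$reference_conditions)
  expect_equal(r1$targets$or, r2$targets$or)
  expect_error(reference_panel_or(md, "target", n_ref = 100, min_cases = 5, seed = 1),
               class = "admixcohort_validation")
})

test_that("case counts tally by category and age group and conserve totals", {
  md <- validate_metadata(data.frame(
    sample = paste0("S", 1:10),
    race = "White", zone = "Z1",
    age = c(5, 10, 16, 17, 3, 30, 45, 50, 8, 12),
    asthma = c("case", "case", "control", "case", NA,
               "case", "control", "case", "case", "control"),
    flu = rep("control", 10)))
  cats <- setNames(rep(c("AFR", "EUR"), 5), md$sample)
  cc <- case_counts_by_group(md, cats, c("asthma", "flu"))
  asthma <- cc[cc$condition == "asthma", ]
  expect_equal(sum(asthma$cases), 6L)
  expect_equal(sum(asthma$cases[asthma$age_group == "child"]), 4L)
  expect_equal(sum(asthma$cases[asthma$category == "AFR"]), 2L)
  expect_equal(cc$cases[cc$condition == "flu"], 0L)
})
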