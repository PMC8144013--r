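tab <- function(a, b, c, d)
  structure(c(a = a, b = b, c = c, d = d), class = "allele_table")

test_that("allele tables count alleles by group", {
  t1 <- allele_table(c(2, 1, 0, 0, 0), c(1, 1, 1, 0, 0))
  expect_equal(unclass(t1), c(a = 3, b = 3, c = 0, d = 4))
  expect_error(allele_table(c(NA, NA), c(1, 0)), "non-missing")
  expect_error(allele_table(c(1, 2), c(1, 1)), "label classes")
})

test_that("X-chromosome males contribute one allele", {
  doses <- c(2, 2, 0, 1)            # two males (0/2), two females
  sex <- c("male", "male", "female", "female")
  labels <- c(1, 0, 1, 0)
  t_x <- allele_table(doses, labels, on_x = TRUE, sex = sex)
  # group 1: male dose 2 -> 1 of 1 allele, female dose 0 -> 0 of 2;
  # group 0: male dose 2 -> 1 of 1, female dose 1 -> 1 of 2
  expect_equal(unclass(t_x), c(a = 1, b = 2, c = 2, d = 1))
})

test_that("allelic chi-squared matches hand value and R's chisq.test", {
  n0 <- allelic_chi2(tab(10, 10, 10, 10))
  expect_equal(n0$chi2, 0)
  expect_equal(n0$p, 1)
  h <- allelic_chi2(tab(6, 4, 4, 6))
  expect_equal(h$chi2, 0.8)
  expect_equal(h$p, 0.3710934, tolerance = 1e-6)
  for (t in random_tables(20, seed = 7)) {
    m <- matrix(unclass(t), 2, byrow = TRUE)
    ref <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    got <- allelic_chi2(t)
    expect_equal(got$chi2, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p, unname(ref$p.value), tolerance = 1e-12)
  }
  expect_error(allelic_chi2(tab(0, 0, 5, 5)), "margin")
})

test_that("chi-squared equals the squared two-proportion z statistic", {
  for (t in random_tables(10, seed = 3)) {
    a <- t[["a"]]; b <- t[["b"]]; cc <- t[["c"]]; d <- t[["d"]]
    p1 <- a / (a + b); p2 <- cc / (cc + d)
    pp <- (a + cc) / (a + b + cc + d)
    z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / (a + b) + 1 / (cc + d)))
    expect_equal(allelic_chi2(t)$chi2, z^2, tolerance = 1e-10)
  }
})

test_that("odds ratios reproduce the published Woolf intervals", {
  r1 <- odds_ratio_ci(tab(539, 607, 1490, 2144))
  expect_equal(round(r1$or, 2), 1.28)
  expect_equal(round(r1$ci_low, 2), 1.12)
  expect_equal(round(r1$ci_high, 2), 1.46)

  r2 <- odds_ratio_ci(tab(13, 25, 509, 3125))
  expect_equal(round(r2$or, 2), 3.19)
  expect_equal(round(r2$ci_low, 2), 1.62)
  expect_equal(round(r2$ci_high, 2), 6.28)

  r0 <- odds_ratio_ci(tab(10, 10, 10, 10))
  expect_equal(r0$or, 1)
  expect_equal(r0$ci_low * r0$ci_high, 1, tolerance = 1e-12)

  rh <- odds_ratio_ci(tab(0, 10, 10, 10))
  expect_true(rh$haldane)
  expect_equal(rh$or, 0.5 * 10.5 / (10.5 * 10.5))
})

test_that("allele flip inverts the OR and mirrors the CI", {
  for (t in random_tables(10, seed = 5)) {
    flipped <- tab(t[["b"]], t[["a"]], t[["d"]], t[["c"]])
    o <- odds_ratio_ci(t); of <- odds_ratio_ci(flipped)
    expect_equal(of$or, 1 / o$or, tolerance = 1e-12)
    expect_equal(of$ci_low, 1 / o$ci_high, tolerance = 1e-12)
    expect_equal(of$ci_high, 1 / o$ci_low, tolerance = 1e-12)
    expect_equal(allelic_chi2(flipped)$chi2, allelic_chi2(t)$chi2,
                 tolerance = 1e-12)
  }
})

test_that("logistic association agrees with the crude fit when sex is absent", {
  set.seed(21)
  dose <- rbinom(300, 2, 0.3)
  y <- rbinom(300, 1, plogis(-1 + 0.5 * dose))
  la <- logistic_assoc(dose, y)
  ref <- glm(y ~ dose, family = binomial())
  expect_equal(la$beta, unname(coef(ref)["dose"]), tolerance = 1e-8)
  expect_false(la$separation)
})

test_that("perfect separation is flagged", {
  dose <- c(rep(2, 10), rep(0, 10))
  y <- c(rep(1, 10), rep(0, 10))
  la <- logistic_assoc(dose, y)
  expect_true(la$separation)
})

test_that("sex-adjusted logistic keeps its nominal type-I error", {
  set.seed(77)
  reject <- logical(300)
  for (i in seq_along(reject)) {
    dose <- rbinom(250, 2, 0.3)
    sex <- sample(c("male", "female"), 250, replace = TRUE)
    y <- rbinom(250, 1, plogis(-1 + 0.7 * (sex == "female")))
    reject[i] <- logistic_assoc(dose, y, sex = sex)$p_adjusted < 0.05
  }
  # binomial(300, 0.05): 3 MC sd is about 0.038
  expect_gt(mean(reject), 0.05 - 0.04)
  expect_lt(mean(reject), 0.05 + 0.04)
})

test_that("Breslow-Day matches an independent root-finding oracle", {
  ident <- breslow_day(list(tab(6, 4, 4, 6), tab(6, 4, 4, 6)))
  expect_lt(ident$statistic, 1e-10)
  expect_equal(ident$p_bd, 1, tolerance = 1e-6)

  opp <- breslow_day(list(tab(20, 5, 5, 20), tab(5, 20, 20, 5)))
  expect_lt(opp$p_bd, 1e-4)

  set.seed(13)
  for (i in 1:20) {
    strata <- random_tables(2, seed = 100 + i)
    got <- breslow_day(strata)
    ref <- bd_oracle(strata)
    expect_equal(got$common_or, ref$common_or, tolerance = 1e-6)
    expect_equal(got$statistic, ref$statistic, tolerance = 1e-6)
    expect_equal(got$p_bd, ref$p, tolerance = 1e-6)
  }
})

test_that("Breslow-Day keeps its size under a homogeneous OR", {
  set.seed(31)
  reject <- logical(200)
  for (i in seq_along(reject)) {
    strata <- lapply(1:2, function(s) {
      dose <- rbinom(400, 2, 0.3)
      y <- rbinom(400, 1, plogis(-1 + log(1.5) * dose))
      allele_table(dose, y)
    })
    reject[i] <- breslow_day(strata)$p_bd < 0.05
  }
  expect_lt(mean(reject), 0.11)
  expect_gt(mean(reject), 0.005)
})

test_that("Breslow-Day input rules: dropped strata and minimum count", {
  expect_warning(
    bd <- breslow_day(list(tab(6, 4, 4, 6), tab(5, 3, 4, 6),
                           tab(0, 0, 4, 6))),
    "dropped")
  expect_equal(bd$n_strata, 2)
  expect_error(suppressWarnings(breslow_day(list(tab(6, 4, 4, 6)))),
               ">= 2")
})

test_that("run_association finds a causal variant and respects min events", {
  v <- panel39()
  v$beta[5] <- log(2)
  cfg <- sim_config(300, 900, v, intercept = qlogis(0.05), seed = 4)
  sc <- simulate_cohort(cfg)
  res <- run_association(sc$cohort, "status")
  expect_s3_class(res, "assoc_result")
  expect_equal(res$id[which.max(res$chi2)], "v05")
  expect_true(all(res$ci_low <= res$or_ & res$or_ <= res$ci_high,
                  na.rm = TRUE))

  ph <- sc$cohort$pheno
  ph$rare_flag <- ifelse(ph$status == "case",
                         c(rep(1, 3), rep(0, 297)), NA)
  co2 <- sc$cohort; co2$pheno <- ph
  expect_error(run_association(co2, "rare_flag"), "fewer than 5")
})

test_that("X variants are analysed by sex strata with an MH common OR", {
  v <- data.frame(id = c("auto1", "vx"), chrom = c("1", "X"),
                  pos = c(1e6, 2e6), maf = c(0.3, 0.25), beta = 0)
  cfg <- sim_config(250, 750, v, seed = 6)
  sc <- simulate_cohort(cfg)
  res <- run_association(sc$cohort, "status")
  rx <- res[res$id == "vx", ]
  expect_true(is.finite(rx$or_))
  expect_true(is.finite(rx$p_asymptotic))
  # cross-check against stats::mantelhaen.test on the same per-sex tables
  labels <- phenotype_labels(sc$cohort, "status")
  g <- sc$cohort$g
  strata <- lapply(c("male", "female"), function(s) {
    sel <- g$sex == s
    allele_table(g$dose[sel, "vx"], labels[sel], on_x = TRUE,
                 sex = g$sex[sel])
  })
  arr <- array(unlist(lapply(strata, function(t)
    rbind(c(t[["a"]], t[["b"]]), c(t[["c"]], t[["d"]])))), c(2, 2, 2))
  # male stratum has 0.5-granular counts; round the array for the oracle
  mh <- stats::mantelhaen.test(round(arr * 2), correct = FALSE)
  expect_equal(rx$or_, unname(mh$estimate), tolerance = 0.02)
})
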