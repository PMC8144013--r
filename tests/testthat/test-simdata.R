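test_that("independent variants follow Hardy-Weinberg at the stated MAF", {
  v <- data.frame(id = "v1", chrom = "1", pos = 100, maf = 0.3)
  cfg <- sim_config(10, 10, v, seed = 60)
  set.seed(60)
  g <- simulate_genotypes(cfg, 10000)
  counts <- table(factor(g$dose[, 1], levels = 0:2)) / 10000
  expected <- c(0.49, 0.42, 0.09)
  se <- sqrt(expected * (1 - expected) / 10000)
  expect_true(all(abs(counts - expected) < 3 * se))
})

test_that("LD blocks hit their target r2 and infeasible targets error", {
  v <- data.frame(id = c("a", "b"), chrom = "1", pos = c(1e6, 1.1e6),
                  maf = 0.3)
  cfg <- sim_config(10, 10, v,
                    ld_blocks = list(list(ids = c("a", "b"), r2 = 0.9)),
                    seed = 61)
  set.seed(61)
  g <- simulate_genotypes(cfg, 5000)
  r2 <- ld_r2(g$dose[, "a"], g$dose[, "b"])
  expect_gt(r2, 0.85); expect_lt(r2, 0.95)

  v_bad <- data.frame(id = c("a", "b"), chrom = "1",
                      pos = c(1e6, 1.1e6), maf = c(0.05, 0.45))
  expect_error(
    sim_config(10, 10, v_bad,
               ld_blocks = list(list(ids = c("a", "b"), r2 = 0.9)),
               seed = 1) |> simulate_genotypes(n = 100),
    "infeasible")
})

test_that("missingness is injected at the requested rate (and only then)", {
  v <- panel39()
  cfg0 <- sim_config(50, 50, v, missing_rate = 0, seed = 62)
  set.seed(62)
  expect_false(anyNA(simulate_genotypes(cfg0, 500)$dose))
  cfg3 <- sim_config(50, 50, v, missing_rate = 0.03, seed = 62)
  set.seed(62)
  miss <- mean(is.na(simulate_genotypes(cfg3, 500)$dose))
  expect_equal(miss, 0.03, tolerance = 0.15)
})

test_that("X-chromosome males carry one simulated allele", {
  v <- data.frame(id = "vx", chrom = "X", pos = 100, maf = 0.25)
  cfg <- sim_config(10, 10, v, seed = 63)
  set.seed(63)
  g <- simulate_genotypes(cfg, 4000)
  male_d <- g$dose[g$sex == "male", 1]
  expect_true(all(male_d %in% c(0, 2)))
  expect_lt(abs(mean(male_d) / 2 - 0.25),
            3 * sqrt(0.25 * 0.75 / length(male_d)))
  female_d <- g$dose[g$sex == "female", 1]
  expect_true(any(female_d == 1))
})

test_that("null generators produce null case-control differences", {
  cfg <- sim_config(400, 1200, panel39(), seed = 64,
                    intercept = qlogis(0.1))
  sc <- simulate_cohort(cfg)
  is_case <- sc$cohort$pheno$status == "case"
  diffs <- vapply(seq_len(39), function(j) {
    compute_maf(sc$cohort$g$dose[is_case, j])$eaf -
      compute_maf(sc$cohort$g$dose[!is_case, j])$eaf
  }, numeric(1))
  expect_lt(max(abs(diffs)), 0.06)
  expect_equal(sum(is_case), 400)
  expect_equal(sum(!is_case), 1200)
})

test_that("a sex effect enriches cases without touching genotypes", {
  cfg <- sim_config(300, 900, panel39(), beta_sex = log(3),
                    intercept = qlogis(0.05), seed = 65)
  sc <- simulate_cohort(cfg)
  ph <- sc$cohort$pheno
  expect_gt(mean(ph$sex[ph$status == "case"] == "female"),
            mean(ph$sex[ph$status == "control"] == "female") + 0.05)
})

test_that("case-only flags honour their models and observed fractions", {
  cfg <- sim_config(500, 500, panel39(), intercept = qlogis(0.5),
                    phenotypes = list(
                      common = list(intercept = qlogis(0.7)),
                      partial = list(intercept = 0, observed = 0.5)),
                    seed = 66)
  sc <- simulate_cohort(cfg)
  ph <- sc$cohort$pheno
  expect_true(all(is.na(ph$common[ph$status == "control"])))
  expect_equal(mean(ph$common[ph$status == "case"], na.rm = TRUE), 0.7,
               tolerance = 0.1)
  obs_frac <- mean(!is.na(ph$partial[ph$status == "case"]))
  expect_equal(obs_frac, 0.5, tolerance = 0.12)
})

test_that("unattainable case quotas fail with actionable advice", {
  cfg <- sim_config(5000, 10, panel39(), intercept = qlogis(1e-4),
                    seed = 67)
  expect_error(simulate_cohort(cfg, max_batches = 2), "intercept")
})

test_that("fixtures are reproducible byte-for-byte under a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- make_fixture("tiny", dir = d1, seed = 99)
  f2 <- make_fixture("tiny", dir = d2, seed = 99)
  for (k in names(f1))
    expect_identical(readLines(f1[[k]]), readLines(f2[[k]]),
                     label = paste("fixture file", k))
})

test_that("the tiny fixture loads through the genotype reader", {
  fx <- make_fixture("tiny", dir = withr::local_tempdir())
  g <- read_genotypes(fx[["genotypes"]], "tsv")
  expect_equal(length(g$samples), 20)
  expect_equal(nrow(g$variants), 3)
  expect_identical(attr(g, "status"),
                   rep(c("case", "control"), each = 10))
})

test_that("the study-shaped fixture matches the printed cohort margins", {
  fx <- make_fixture("study-shape", dir = withr::local_tempdir())
  obj <- attr(fx, "objects")
  expect_equal(sum(obj$pheno$status == "case"), 625)
  expect_equal(sum(obj$pheno$status == "control"), 1817)
  ctrl <- obj$pheno$status == "control"
  maf_ctrl <- compute_maf(obj$g$dose[ctrl, "rs653178"])$maf
  # binomial sampling error at 2 * 1817 alleles: 3 s.e. is about 0.025
  expect_lt(abs(maf_ctrl - 0.41), 3 * sqrt(0.41 * 0.59 / (2 * 1817)))
  expect_equal(sum(obj$pheno$diagnosed_gt7, na.rm = TRUE), 573)
  # generated data passes the default QC filters
  co <- suppressMessages(join_cohort(obj$g, obj$pheno))
  res <- apply_filters(co)
  expect_true(all(res$report$pass))
})

test_that("a truth-weighted score separates simulated cases from controls", {
  v <- panel39()
  v$beta <- log(seq(1.1, 1.5, length.out = 39))
  aucs <- vapply(1:20, function(i) {
    cfg <- sim_config(150, 450, v, intercept = qlogis(0.03),
                      seed = 700 + i)
    sc <- simulate_cohort(cfg)
    w <- data.frame(id = v$id, effect_allele = "A", beta = v$beta)
    prof <- wgrs(align_to_effect_allele(sc$cohort$g, w), w)
    case <- sc$cohort$pheno$status == "case"
    # AUC via the rank-sum identity
    r <- rank(prof$score)
    (sum(r[case]) - sum(case) * (sum(case) + 1) / 2) /
      (sum(case) * sum(!case))
  }, numeric(1))
  expect_gt(mean(aucs), 0.5)
  expect_lt(stats::t.test(aucs, mu = 0.5,
                          alternative = "greater")$p.value, 0.05)
})
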