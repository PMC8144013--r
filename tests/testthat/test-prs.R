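test_that("composite LD behaves as squared correlation of doses", {
  set.seed(50)
  d <- rbinom(500, 2, 0.3)
  expect_equal(ld_r2(d, d), 1)
  expect_equal(ld_r2(d, 2 - d), 1)     # linear map keeps r^2
  ind1 <- rbinom(2000, 2, 0.3)
  ind2 <- rbinom(2000, 2, 0.4)
  expect_lt(ld_r2(ind1, ind2), 0.01)
  expect_warning(r0 <- ld_r2(rep(1, 10), rbinom(10, 2, 0.5)),
                 "zero dose variance")
  expect_equal(r0, 0)
  expect_error(ld_r2(c(1, NA), c(NA, 1)), ">= 2 samples")
})

test_that("clumping keeps the most significant variant of a tight block", {
  v <- data.frame(id = c("lead", "mid", "weak"), chrom = "2",
                  pos = c(1e6, 1.05e6, 1.1e6), maf = 0.3)
  cfg <- sim_config(10, 10, v,
                    ld_blocks = list(list(ids = v$id, r2 = 0.9)),
                    seed = 51)
  set.seed(51)
  g <- simulate_genotypes(cfg, 2000)
  ss <- data.frame(id = v$id, chrom = v$chrom, pos = v$pos,
                   effect_allele = "A", beta = 0.2,
                   p = c(1e-8, 1e-4, 1e-2))
  expect_equal(clump(ss, g), "lead")
  expect_equal(clump(ss[1, ], g), "lead")   # single variant trivially kept
})

test_that("the MHC long-range-LD interval is excluded before clumping", {
  v <- data.frame(id = c("mhc_in", "mhc_edge", "chr6_out"), chrom = "6",
                  pos = c(31e6, 33.3e6, 34e6), maf = 0.3)
  cfg <- sim_config(10, 10, v, seed = 52)
  set.seed(52)
  g <- simulate_genotypes(cfg, 500)
  ss <- data.frame(id = v$id, chrom = "6", pos = v$pos,
                   effect_allele = "A", beta = 0.1, p = c(1e-8, 1e-6, 0.5))
  kept <- clump(ss, g)
  expect_false("mhc_in" %in% kept)
  expect_false("mhc_edge" %in% kept)  # closed interval at 33.3 Mb
  expect_true("chr6_out" %in% kept)
})

test_that("clumped sets satisfy the brute-force post-conditions", {
  fx <- make_fixture("ld-demo", dir = withr::local_tempdir())
  obj <- attr(fx, "objects")
  g <- obj$g; ss <- obj$sumstats
  cfg <- clump_config()
  kept <- clump(ss, g, cfg)
  kept_ss <- ss[ss$id %in% kept, ]
  # pairwise independence of the retained set
  for (i in seq_len(nrow(kept_ss))) for (j in seq_len(nrow(kept_ss))) {
    if (i >= j) next
    if (kept_ss$chrom[i] != kept_ss$chrom[j]) next
    if (abs(kept_ss$pos[i] - kept_ss$pos[j]) > cfg$window_kb * 1000) next
    expect_lte(ld_r2(g$dose[, kept_ss$id[i]], g$dose[, kept_ss$id[j]]),
               cfg$r2_max)
  }
  # every removed variant has a better retained neighbour in LD
  removed <- ss[!ss$id %in% kept &
                  !(ss$chrom == "6" & ss$pos >= 29.7e6 &
                      ss$pos <= 33.3e6), ]
  for (i in seq_len(nrow(removed))) {
    nb <- kept_ss[kept_ss$chrom == removed$chrom[i] &
                    abs(kept_ss$pos - removed$pos[i]) <=
                    cfg$window_kb * 1000 &
                    kept_ss$p <= removed$p[i], ]
    r2s <- vapply(nb$id, function(id)
      ld_r2(g$dose[, id], g$dose[, removed$id[i]]), numeric(1))
    expect_true(any(r2s > cfg$r2_max),
                label = paste("removed", removed$id[i],
                              "has a dominating neighbour"))
  }
})

test_that("PRS scoring weights doses and imputes missing by frequency", {
  dose <- matrix(c(2, 0, NA), 3, 1,
                 dimnames = list(c("s1", "s2", "s3"), "v1"))
  g <- genotype_matrix(dose, data.frame(
    id = "v1", chrom = "1", pos = 100, allele_a = "A", allele_b = "G"))
  ss <- data.frame(id = "v1", chrom = "1", pos = 100,
                   effect_allele = "A", beta = 0.5, p = 0.01)
  s <- prs_score(g, ss, retained = "v1", threshold = 0.05)
  expect_equal(unname(s["s1"]), 1.0)
  expect_equal(unname(s["s3"]), 0.5 * 1)  # mean dose of s1,s2 is 1
  expect_equal(attr(s, "n_imputed"), 1)
  expect_warning(s0 <- prs_score(g, ss, "v1", threshold = 0.001),
                 "no variants")
  expect_true(all(s0 == 0))
})

test_that("threshold ladders nest after a single clumping pass", {
  fx <- make_fixture("ld-demo", dir = withr::local_tempdir())
  obj <- attr(fx, "objects")
  ladder <- prs_ladder(obj$g, obj$sumstats)
  n_snps <- vapply(ladder, attr, integer(1), "n_snps")
  expect_true(all(diff(n_snps) >= 0))
  retained <- attr(ladder, "retained")
  ss <- obj$sumstats
  for (th in c(0.01, 0.2)) {
    ids_low <- ss$id[ss$id %in% retained & ss$p < th]
    ids_high <- ss$id[ss$id %in% retained & ss$p < 0.5]
    expect_true(all(ids_low %in% ids_high))
  }
})

test_that("prs_fit reports non-negative delta-R2 and a valid empirical P", {
  fx <- make_fixture("ld-demo", dir = withr::local_tempdir())
  obj <- attr(fx, "objects")
  ladder <- prs_ladder(obj$g, obj$sumstats)
  n <- length(obj$g$samples)
  set.seed(53)
  covars <- data.frame(age = runif(n, 5, 75), sex = obj$g$sex)
  y <- rbinom(n, 1, plogis(-1 + as.vector(scale(ladder[["0.3"]]))))
  plan <- permutation_plan(n_perm = 49, seed = 54)
  fit <- prs_fit(ladder, y, covars, plan)
  expect_true(all(fit$fits$r2_delta >= 0))
  expect_gte(fit$emp_p, 1 / 50)
  expect_lte(fit$emp_p, 1)
  expect_true(fit$best %in% fit$fits$threshold)
  # signal planted at 0.3: the best threshold should carry real signal
  expect_lte(fit$fits$p[fit$fits$threshold == fit$best], 1e-3)
  fit2 <- prs_fit(ladder, y, covars, plan)
  expect_identical(fit$emp_p, fit2$emp_p)
})

test_that("a score orthogonal to the phenotype explains ~zero variance", {
  set.seed(55)
  n <- 600
  y <- rbinom(n, 1, 0.4)
  raw <- rnorm(n)
  # orthogonalise against the phenotype (and the intercept)
  ortho <- residuals(lm(raw ~ y))
  covars <- data.frame(age = runif(n, 1, 80))
  f <- prs_fit(list(`0.5` = ortho), y, covars,
               permutation_plan(n_perm = 9, seed = 56))
  expect_lt(f$fits$r2_delta, 1e-3)
  expect_error(prs_fit(list(`0.5` = ortho), rep(1, n), covars,
                       permutation_plan(9, 1)), "constant")
})
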