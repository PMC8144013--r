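# Independent oracles, implemented by different routes than the package.

# Exact HWE P by direct enumeration: conditional probability of each
# feasible heterozygote count from log-factorials (no recurrence).
hwe_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  n_a <- 2 * n_hom_alt + n_het
  n_b <- 2 * n_hom_ref + n_het
  if (n_a > n_b) { tmp <- n_a; n_a <- n_b; n_b <- tmp }
  if (n_a == 0) return(1)
  hets <- seq(n_a %% 2, n_a, by = 2)
  logp <- vapply(hets, function(h) {
    naa <- (n_a - h) / 2
    nbb <- (n_b - h) / 2
    lfactorial(n) - lfactorial(naa) - lfactorial(h) - lfactorial(nbb) +
      h * log(2) + lfactorial(n_a) + lfactorial(n_b) -
      lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[hets == n_het]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

# Breslow-Day statistic with expected cell counts found by root-finding on
# the odds-ratio equation (not the closed-form quadratic), and the common
# OR taken from stats::mantelhaen.test.
bd_oracle <- function(strata) {
  arr <- array(unlist(lapply(strata, function(t)
    rbind(c(t[["a"]], t[["b"]]), c(t[["c"]], t[["d"]])))),
    dim = c(2, 2, length(strata)))
  or_mh <- unname(stats::mantelhaen.test(arr, correct = FALSE)$estimate)
  stat <- 0
  for (t in strata) {
    a <- t[["a"]]; b <- t[["b"]]; cc <- t[["c"]]; d <- t[["d"]]
    r1 <- a + b; c1 <- a + cc; n <- a + b + cc + d
    lo <- max(0, r1 + c1 - n) + 1e-9
    hi <- min(r1, c1) - 1e-9
    f <- function(A)
      A * (n - r1 - c1 + A) / ((r1 - A) * (c1 - A)) - or_mh
    A <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
    v <- 1 / (1 / A + 1 / (r1 - A) + 1 / (c1 - A) +
                1 / (n - r1 - c1 + A))
    stat <- stat + (a - A)^2 / v
  }
  list(statistic = stat,
       p = stats::pchisq(stat, df = length(strata) - 1,
                         lower.tail = FALSE),
       common_or = or_mh)
}

# Exhaustive pointwise permutation tail for one variant on a toy cohort:
# enumerate every case assignment, count the allele table naively.
emp1_oracle <- function(doses, n_cases) {
  n <- length(doses)
  stat_of <- function(case_idx) {
    a <- b <- cc <- d <- 0
    for (i in seq_len(n)) {
      if (i %in% case_idx) {
        a <- a + doses[i]; b <- b + (2 - doses[i])
      } else {
        cc <- cc + doses[i]; d <- d + (2 - doses[i])
      }
    }
    tot <- a + b + cc + d
    den <- (a + b) * (cc + d) * (a + cc) * (b + d)
    if (den <= 0) return(0)
    tot * (a * d - b * cc)^2 / den
  }
  combos <- utils::combn(n, n_cases, simplify = FALSE)
  stats_all <- vapply(combos, stat_of, numeric(1))
  obs <- stat_of(seq_len(n_cases))
  mean(stats_all >= obs - 1e-12)
}

# Random 2x2 tables with all-positive cells.
random_tables <- function(n, seed, max_cell = 40) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    cells <- sample(1:max_cell, 4, replace = TRUE)
    structure(c(a = cells[1], b = cells[2], c = cells[3], d = cells[4]),
              class = "allele_table")
  })
}

# Null case-control cohort: genotypes independent of fixed labels.
null_cohort <- function(n_cases, n_controls, variants, seed) {
  cfg <- sim_config(n_cases, n_controls, variants, seed = seed)
  set.seed(seed)
  g <- simulate_genotypes(cfg, n = n_cases + n_controls)
  ph <- data.frame(sample_id = g$samples,
                   status = rep(c("case", "control"),
                                c(n_cases, n_controls)),
                   sex = g$sex, stringsAsFactors = FALSE)
  suppressMessages(join_cohort(g, ph))
}

panel39 <- function() {
  data.frame(id = sprintf("v%02d", 1:39), chrom = "1",
             pos = 1e6 * (1:39),
             maf = rep(c(0.1, 0.2, 0.3, 0.4, 0.5), 8)[1:39],
             beta = 0, stringsAsFactors = FALSE)
}
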