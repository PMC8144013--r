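#' Synthetic cohort configuration
#'
#' Describes the generating model of a case-control cohort: variant panel
#' (MAFs, per-variant disease log-ORs), optional LD blocks (common target
#' pairwise r-squared per block, achieved through a shared latent factor
#' per haplotype), X-chromosome handling (males carry one allele, dose
#' 0/2), an additive logistic disease model with a sex covariate, and
#' case-only sub-phenotype models.
#'
#' @param n_cases,n_controls target sample counts.
#' @param variants data.frame: `id`, `chrom`, `pos`, `maf` in (0, 0.5],
#'   `beta` (disease log-OR per effect allele, default 0).
#' @param ld_blocks list of `list(ids = <variant ids>, r2 = <target>)`.
#' @param sex_ratio proportion of females (default 0.5).
#' @param intercept disease-model intercept on the logit scale (default
#'   `qlogis(0.02)`, a few-percent baseline prevalence so case-control
#'   ascertainment behaves like a rare-ish disease).
#' @param beta_sex log-OR of female sex on disease (default 0).
#' @param phenotypes named list of case-only flag models, each
#'   `list(intercept =, beta_sex = 0, beta_age = 0, betas = c(id = logOR),
#'   observed = 1)`; `observed` < 1 leaves the flag missing for a random
#'   subset, mirroring partial phenotype denominators.
#' @param missing_rate genotype missingness, completely at random.
#' @param age_range ages drawn uniformly from this interval (years).
#' @param seed integer root seed.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(n_cases, n_controls, variants,
                       ld_blocks = list(), sex_ratio = 0.5,
                       intercept = stats::qlogis(0.02), beta_sex = 0,
                       phenotypes = list(), missing_rate = 0,
                       age_range = c(0.5, 79), seed = 1) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (is.null(variants$beta)) variants$beta <- 0
  stopifnot(all(variants$maf > 0), all(variants$maf <= 0.5),
            missing_rate >= 0, missing_rate < 1,
            sex_ratio >= 0, sex_ratio <= 1)
  for (b in ld_blocks) {
    stopifnot(all(b$ids %in% variants$id), b$r2 >= 0, b$r2 < 1)
  }
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 variants = variants, ld_blocks = ld_blocks,
                 sex_ratio = sex_ratio, intercept = intercept,
                 beta_sex = beta_sex, phenotypes = phenotypes,
                 missing_rate = missing_rate, age_range = age_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# P(Z1 > t1, Z2 > t2) under a shared-factor latent model with loading
# sqrt(rho) on both variables (pairwise latent correlation rho).
bivariate_upper <- function(t1, t2, rho) {
  if (rho <= 0) return(stats::pnorm(t1, lower.tail = FALSE) *
                         stats::pnorm(t2, lower.tail = FALSE))
  s <- sqrt(1 - rho)
  stats::integrate(function(f) {
    stats::dnorm(f) *
      stats::pnorm((t1 - sqrt(rho) * f) / s, lower.tail = FALSE) *
      stats::pnorm((t2 - sqrt(rho) * f) / s, lower.tail = FALSE)
  }, -8, 8, rel.tol = 1e-9)$value
}

# Latent correlation giving haplotype-indicator correlation r_target
# between two alleles with frequencies p1, p2.
latent_rho_for_r <- function(p1, p2, r_target) {
  if (r_target <= 0) return(0)
  t1 <- stats::qnorm(1 - p1); t2 <- stats::qnorm(1 - p2)
  f <- function(rho) {
    p11 <- bivariate_upper(t1, t2, rho)
    (p11 - p1 * p2) / sqrt(p1 * (1 - p1) * p2 * (1 - p2)) - r_target
  }
  hi <- f(0.999999)
  if (hi < 0)
    stop("target r^2 infeasible for allele frequencies ",
         signif(p1, 3), " and ", signif(p2, 3))
  stats::uniroot(f, c(0, 0.999999), tol = 1e-8)$root
}

# One haplotype's allele indicators for a block of variants sharing a
# latent factor; thresholds per variant at qnorm(1 - maf).
block_haplotypes <- function(n, mafs, rho) {
  k <- length(mafs)
  f <- stats::rnorm(n)
  z <- sqrt(rho) * f +
    sqrt(1 - rho) * matrix(stats::rnorm(n * k), n, k)
  t(t(z) > stats::qnorm(1 - mafs)) * 1
}

#' Simulate genotypes under the configuration
#'
#' Independent variants are drawn under Hardy-Weinberg equilibrium at
#' their MAF (binomial(2, maf); on X, females binomial(2), males one
#' allele coded 0/2). LD blocks draw each haplotype's alleles from a
#' shared latent Gaussian factor thresholded at the allele frequency; the
#' factor loading is solved numerically so the haplotype (and hence dose)
#' correlation matches `sqrt(r2)`. Missingness is injected completely at
#' random. The caller controls the RNG state (see [simulate_cohort()]).
#'
#' @param cfg a [sim_config()].
#' @param n number of samples (default `n_cases + n_controls`).
#' @param sex optional precomputed sex vector.
#' @return A [genotype_matrix()] (allele_a = effect allele "A",
#'   allele_b = "G").
#' @export
simulate_genotypes <- function(cfg, n = cfg$n_cases + cfg$n_controls,
                               sex = NULL) {
  v <- cfg$variants
  m <- nrow(v)
  if (is.null(sex))
    sex <- ifelse(stats::runif(n) < cfg$sex_ratio, "female", "male")
  female <- sex == "female"
  in_block <- rep(FALSE, m)
  dose <- matrix(0, n, m)

  for (b in cfg$ld_blocks) {
    j <- match(b$ids, v$id)
    in_block[j] <- TRUE
    mafs <- v$maf[j]
    r_hap <- sqrt(b$r2)
    # feasibility: the most extreme frequency pair caps the attainable
    # correlation of threshold indicators
    pmin_ <- min(mafs); pmax_ <- max(mafs)
    r_cap <- sqrt(pmin_ * (1 - pmax_) / ((1 - pmin_) * pmax_))
    if (r_hap > r_cap + 1e-9)
      stop("LD block [", paste(b$ids, collapse = ","),
           "]: target r^2 ", b$r2, " infeasible for MAF range ",
           signif(pmin_, 3), "-", signif(pmax_, 3))
    # common loading from the average threshold; exact when the block's
    # MAFs are equal, approximate otherwise
    rho <- tryCatch(
      latent_rho_for_r(mean(mafs), mean(mafs), r_hap),
      error = function(e)
        stop("LD block [", paste(b$ids, collapse = ","), "]: ",
             conditionMessage(e)))
    on_x <- v$chrom[j] == "X"
    if (any(on_x) && !all(on_x))
      stop("LD block mixing X and autosomal variants: ",
           paste(b$ids, collapse = ","))
    if (all(on_x)) {
      h1 <- block_haplotypes(n, mafs, rho)
      h2 <- block_haplotypes(n, mafs, rho)
      dose[female, j] <- h1[female, , drop = FALSE] +
        h2[female, , drop = FALSE]
      dose[!female, j] <- 2 * h1[!female, , drop = FALSE]
    } else {
      dose[, j] <- block_haplotypes(n, mafs, rho) +
        block_haplotypes(n, mafs, rho)
    }
  }

  for (j in which(!in_block)) {
    if (v$chrom[j] == "X") {
      d <- numeric(n)
      d[female] <- stats::rbinom(sum(female), 2, v$maf[j])
      d[!female] <- 2 * stats::rbinom(sum(!female), 1, v$maf[j])
      dose[, j] <- d
    } else {
      dose[, j] <- stats::rbinom(n, 2, v$maf[j])
    }
  }

  if (cfg$missing_rate > 0)
    dose[stats::runif(n * m) < cfg$missing_rate] <- NA

  variants <- data.frame(id = v$id, chrom = as.character(v$chrom),
                         pos = v$pos, allele_a = "A", allele_b = "G",
                         stringsAsFactors = FALSE)
  rownames(dose) <- sprintf("S%05d", seq_len(n))
  genotype_matrix(dose, variants, sex)
}

#' Simulate phenotypes for a genotype matrix
#'
#' Disease status follows the additive logistic model
#' `logit P(case) = intercept + sum(beta_v * dose_v) + beta_sex * female`.
#' Case-only sub-phenotype flags are then drawn from their own logistic
#' models (controls carry `NA` flags), optionally left unobserved for a
#' random fraction to mirror partial phenotype availability. Missing doses
#' contribute their expected value (2 x MAF) to the liability.
#'
#' @param g a [genotype_matrix()] from [simulate_genotypes()].
#' @param cfg the same [sim_config()].
#' @return data.frame: `sample_id`, `status`, `sex`, `age`,
#'   `age_at_diagnosis`, one column per configured flag; attribute
#'   `liability` carries the disease-model linear predictor.
#' @export
simulate_phenotypes <- function(g, cfg) {
  n <- length(g$samples)
  v <- cfg$variants
  D <- g$dose[, match(v$id, g$variants$id), drop = FALSE]
  for (j in seq_len(ncol(D)))
    D[is.na(D[, j]), j] <- 2 * v$maf[j]
  female <- as.numeric(g$sex == "female")
  lp <- cfg$intercept + as.vector(D %*% v$beta) + cfg$beta_sex * female
  status <- ifelse(stats::runif(n) < stats::plogis(lp),
                   "case", "control")
  age <- stats::runif(n, cfg$age_range[1], cfg$age_range[2])
  out <- data.frame(sample_id = g$samples, status = status,
                    sex = g$sex, age = age,
                    age_at_diagnosis = ifelse(status == "case",
                                              age * stats::runif(n), NA),
                    stringsAsFactors = FALSE)
  is_case <- status == "case"
  for (nm in names(cfg$phenotypes)) {
    ph <- cfg$phenotypes[[nm]]
    betas <- ph$betas %||% numeric(0)
    contrib <- if (length(betas)) {
      as.vector(D[, match(names(betas), v$id), drop = FALSE] %*% betas)
    } else 0
    lpf <- ph$intercept + (ph$beta_sex %||% 0) * female +
      (ph$beta_age %||% 0) * age + contrib
    flag <- ifelse(stats::runif(n) < stats::plogis(lpf), 1, 0)
    flag[!is_case] <- NA
    observed <- ph$observed %||% 1
    if (observed < 1)
      flag[is_case & stats::runif(n) > observed] <- NA
    out[[nm]] <- flag
  }
  attr(out, "liability") <- lp
  out
}

#' Simulate a full ascertained case-control cohort
#'
#' Case-control studies oversample cases, so the generator draws genotype
#' batches from the population model, assigns disease status, and keeps
#' sampling until both the case and control quotas are met (rejection
#' sampling against the ascertainment targets). Fails with advice if the
#' disease model cannot plausibly produce enough cases.
#'
#' @param cfg a [sim_config()].
#' @param max_batches safety bound on the number of batches (default 60).
#' @return List of class `"sim_cohort"`: `cohort` (a [join_cohort()]
#'   result with `n_cases + n_controls` samples) and `truth` (the config
#'   plus realised liabilities).
#' @export
simulate_cohort <- function(cfg, max_batches = 60) {
  set.seed(cfg$seed)
  target_n <- cfg$n_cases + cfg$n_controls
  prev_guess <- stats::plogis(cfg$intercept +
                                sum(2 * cfg$variants$maf *
                                      cfg$variants$beta))
  batch <- max(1000L,
               ceiling(1.5 * max(cfg$n_cases / max(prev_guess, 1e-4),
                                 cfg$n_controls)))
  batch <- min(batch, 200000L)
  got_case <- got_ctrl <- 0L
  g_parts <- list(); p_parts <- list(); lp_parts <- list()
  for (i in seq_len(max_batches)) {
    g <- simulate_genotypes(cfg, n = batch)
    ph <- simulate_phenotypes(g, cfg)
    is_case <- ph$status == "case"
    need_case <- cfg$n_cases - got_case
    need_ctrl <- cfg$n_controls - got_ctrl
    take <- c(which(is_case)[seq_len(min(need_case, sum(is_case)))],
              which(!is_case)[seq_len(min(need_ctrl, sum(!is_case)))])
    if (length(take)) {
      g_parts[[length(g_parts) + 1]] <-
        list(dose = g$dose[take, , drop = FALSE], sex = g$sex[take])
      p_parts[[length(p_parts) + 1]] <- ph[take, , drop = FALSE]
      lp_parts[[length(lp_parts) + 1]] <- attr(ph, "liability")[take]
      got_case <- got_case + min(need_case, sum(is_case))
      got_ctrl <- got_ctrl + min(need_ctrl, sum(!is_case))
    }
    if (got_case >= cfg$n_cases && got_ctrl >= cfg$n_controls) break
  }
  if (got_case < cfg$n_cases || got_ctrl < cfg$n_controls)
    stop("could not reach ", cfg$n_cases, " cases / ", cfg$n_controls,
         " controls in ", max_batches, " batches; raise the disease-model ",
         "intercept or the batch bound")
  dose <- do.call(rbind, lapply(g_parts, `[[`, "dose"))
  sex <- unlist(lapply(g_parts, `[[`, "sex"))
  pheno <- do.call(rbind, p_parts)
  ids <- sprintf("S%05d", seq_len(nrow(dose)))
  rownames(dose) <- ids
  pheno$sample_id <- ids
  rownames(pheno) <- NULL
  v <- cfg$variants
  g <- genotype_matrix(
    dose,
    data.frame(id = v$id, chrom = as.character(v$chrom), pos = v$pos,
               allele_a = "A", allele_b = "G", stringsAsFactors = FALSE),
    sex)
  cohort <- suppressMessages(join_cohort(g, pheno))
  structure(list(cohort = cohort,
                 truth = list(config = cfg,
                              liability = unlist(lp_parts))),
            class = "sim_cohort")
}
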