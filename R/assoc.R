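#' Build the 2x2 allele table for one variant
#'
#' Counts effect vs other alleles in the two label groups. Autosomes: a
#' sample contributes two alleles, `a = sum(dose)` among `label == 1`.
#' Chromosome X: counts are accumulated per sex — females contribute two
#' alleles, hemizygous males one (dose/2) — and then summed, so male
#' carriers are never double-counted.
#'
#' @param doses per-sample effect-allele counts for one variant.
#' @param labels binary vector (1 = group of interest, 0 = reference,
#'   `NA` excluded).
#' @param on_x is the variant on chromosome X?
#' @param sex per-sample sex, required when `on_x`.
#' @return Named numeric of class `"allele_table"`: `a`, `b` (effect/other
#'   alleles in group 1), `c`, `d` (group 0).
#' @export
allele_table <- function(doses, labels, on_x = FALSE, sex = NULL) {
  keep <- !is.na(doses) & !is.na(labels)
  if (!any(keep)) stop("no usable (non-missing) genotype/label pairs")
  doses <- doses[keep]; labels <- labels[keep]
  if (on_x) {
    if (is.null(sex)) stop("sex required for X-chromosome allele counts")
    sex <- sex[keep]
    allele_dose <- ifelse(sex == "male", doses / 2, doses)
    n_alleles <- ifelse(sex == "male", 1, 2)
  } else {
    allele_dose <- doses
    n_alleles <- rep(2, length(doses))
  }
  if (!any(labels == 1) || !any(labels == 0))
    stop("both label classes must be non-empty")
  a <- sum(allele_dose[labels == 1])
  b <- sum(n_alleles[labels == 1]) - a
  cc <- sum(allele_dose[labels == 0])
  d <- sum(n_alleles[labels == 0]) - cc
  structure(c(a = a, b = b, c = cc, d = d), class = "allele_table")
}

#' Allelic chi-squared test (1 df, no continuity correction)
#'
#' @param t an [allele_table()] (or any numeric with elements a, b, c, d).
#' @return List with `chi2` and `p` (upper tail, 1 df).
#' @export
allelic_chi2 <- function(t) {
  a <- t[["a"]]; b <- t[["b"]]; cc <- t[["c"]]; d <- t[["d"]]
  n <- a + b + cc + d
  if (min(a + b, cc + d, a + cc, b + d) <= 0)
    stop("zero margin: allelic chi-squared undefined")
  chi2 <- n * (a * d - b * cc)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
  list(chi2 = unname(chi2),
       p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Odds ratio with Woolf confidence interval
#'
#' `OR = ad/bc`; CI on the log scale, `exp(log OR +/- z * sqrt(1/a + 1/b +
#' 1/c + 1/d))`. Any zero cell triggers the Haldane-Anscombe correction
#' (0.5 added to every cell) and the result is flagged.
#'
#' @param t an [allele_table()].
#' @param level confidence level (default 0.95).
#' @return List with `or`, `ci_low`, `ci_high`, `haldane` (logical flag).
#' @export
odds_ratio_ci <- function(t, level = 0.95) {
  a <- t[["a"]]; b <- t[["b"]]; cc <- t[["c"]]; d <- t[["d"]]
  haldane <- any(c(a, b, cc, d) == 0)
  if (haldane) { a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * cc)
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  list(or = or, ci_low = or * exp(-z * se), ci_high = or * exp(z * se),
       haldane = haldane)
}

#' Sex-adjusted logistic association for one variant
#'
#' Fits `label ~ dose + sex` (binomial, logit link, additive dose coding)
#' by maximum likelihood and reports the per-dose odds ratio with its Wald
#' P. With `interaction = TRUE` a `dose:sex` term is added and its Wald P
#' reported too. Quasi-separation is flagged by fitted probabilities
#' numerically at 0/1.
#'
#' @param doses effect-allele counts.
#' @param labels binary outcome.
#' @param sex optional covariate (factor or character); omitted if all one
#'   level.
#' @param interaction add a dose x sex interaction term?
#' @return List: `or_adjusted`, `beta`, `se`, `p_adjusted`,
#'   `p_interaction` (NA unless requested), `converged`, `separation`.
#' @export
logistic_assoc <- function(doses, labels, sex = NULL, interaction = FALSE) {
  keep <- !is.na(doses) & !is.na(labels)
  df <- data.frame(y = labels[keep], dose = doses[keep])
  use_sex <- !is.null(sex)
  if (use_sex) {
    df$sex <- factor(sex[keep])
    if (nlevels(droplevels(df$sex)) < 2) use_sex <- FALSE
  }
  form <- if (!use_sex) y ~ dose
  else if (interaction) y ~ dose * sex else y ~ dose + sex
  fit <- suppressWarnings(
    stats::glm(form, family = stats::binomial(), data = df))
  co <- summary(fit)$coefficients
  eps <- 1e-8
  separation <- any(fit$fitted.values < eps | fit$fitted.values > 1 - eps)
  p_int <- NA_real_
  if (interaction && use_sex) {
    int_row <- grep("^dose:", rownames(co))
    if (length(int_row)) p_int <- co[int_row[1], 4]
  }
  list(or_adjusted = unname(exp(co["dose", 1])),
       beta = unname(co["dose", 1]), se = unname(co["dose", 2]),
       p_adjusted = unname(co["dose", 4]),
       p_interaction = p_int,
       converged = fit$converged, separation = separation)
}

usable_stratum <- function(t) {
  min(t[["a"]] + t[["b"]], t[["c"]] + t[["d"]],
      t[["a"]] + t[["c"]], t[["b"]] + t[["d"]]) > 0
}

#' Breslow-Day test of odds-ratio homogeneity across strata
#'
#' Computes the Mantel-Haenszel common odds ratio and the Breslow-Day
#' statistic `sum_k (a_k - E[a_k | OR_MH])^2 / Var(a_k | OR_MH)` on
#' `K - 1` degrees of freedom (no Tarone correction). Strata with a zero
#' margin are dropped with a warning.
#'
#' @param strata list of [allele_table()]s (e.g. one per sex).
#' @return List: `p_bd`, `statistic`, `df`, `common_or`, `n_strata`.
#' @export
breslow_day <- function(strata) {
  usable <- vapply(strata, usable_stratum, logical(1))
  if (any(!usable))
    warning(sum(!usable), " stratum/strata with zero margin dropped")
  strata <- strata[usable]
  k <- length(strata)
  if (k < 2) stop("Breslow-Day needs >= 2 usable strata")
  tab <- do.call(rbind, lapply(strata, unclass))
  n <- rowSums(tab)
  or_mh <- sum(tab[, "a"] * tab[, "d"] / n) /
    sum(tab[, "b"] * tab[, "c"] / n)
  stat <- 0
  for (i in seq_len(k)) {
    a <- tab[i, "a"]; b <- tab[i, "b"]; cc <- tab[i, "c"]; d <- tab[i, "d"]
    r1 <- a + b; c1 <- a + cc; nn <- a + b + cc + d
    A <- expected_a_given_or(r1, c1, nn, or_mh)
    v <- 1 / (1 / A + 1 / (r1 - A) + 1 / (c1 - A) + 1 / (nn - r1 - c1 + A))
    stat <- stat + (a - A)^2 / v
  }
  stat <- unname(stat)
  list(p_bd = stats::pchisq(stat, df = k - 1, lower.tail = FALSE),
       statistic = stat, df = k - 1, common_or = unname(or_mh),
       n_strata = k)
}

# Expected count in cell (1,1) of a 2x2 table with margins (r1, c1, n)
# and odds ratio psi: root of the quadratic
#   A^2 (psi - 1) - A [psi (r1 + c1) + n - r1 - c1] + psi r1 c1 = 0
# inside (max(0, r1 + c1 - n), min(r1, c1)).
expected_a_given_or <- function(r1, c1, n, psi) {
  if (abs(psi - 1) < 1e-12) return(r1 * c1 / n)
  qa <- psi - 1
  qb <- -(psi * (r1 + c1) + n - r1 - c1)
  qc <- psi * r1 * c1
  disc <- sqrt(qb^2 - 4 * qa * qc)
  roots <- c((-qb - disc) / (2 * qa), (-qb + disc) / (2 * qa))
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  ok <- roots > lo & roots < hi
  if (!any(ok)) stop("no admissible root for expected cell count")
  roots[ok][1]
}

#' Cochran-Mantel-Haenszel association across strata
#'
#' The 1-df CMH statistic (no continuity correction) with the MH common OR
#' and its Robins-Breslow-Greenland confidence interval; used for
#' X-chromosome variants, where male and female allele counts form separate
#' strata.
#'
#' @param strata list of [allele_table()]s.
#' @param level confidence level.
#' @return List: `chi2`, `p`, `or`, `ci_low`, `ci_high`.
#' @export
cmh_assoc <- function(strata, level = 0.95) {
  usable <- vapply(strata, usable_stratum, logical(1))
  strata <- strata[usable]
  if (!length(strata)) stop("no usable strata")
  tab <- do.call(rbind, lapply(strata, unclass))
  a <- tab[, "a"]; b <- tab[, "b"]; cc <- tab[, "c"]; d <- tab[, "d"]
  n <- a + b + cc + d
  num <- sum(a - (a + b) * (a + cc) / n)
  den <- sum((a + b) * (cc + d) * (a + cc) * (b + d) / (n^2 * (n - 1)))
  chi2 <- num^2 / den
  R <- a * d / n; S <- b * cc / n
  or <- sum(R) / sum(S)
  # Robins-Breslow-Greenland variance of log OR_MH
  P <- (a + d) / n; Q <- (b + cc) / n
  v <- sum(P * R) / (2 * sum(R)^2) +
    sum(P * S + Q * R) / (2 * sum(R) * sum(S)) +
    sum(Q * S) / (2 * sum(S)^2)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(chi2 = unname(chi2),
       p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       or = unname(or), ci_low = unname(or * exp(-z * sqrt(v))),
       ci_high = unname(or * exp(z * sqrt(v))))
}

#' Phenotype contrast labels for a cohort
#'
#' Table-2-style contrasts compare phenotype-positive cases with all
#' population controls: label 1 for cases carrying the flag, 0 for
#' controls, `NA` (excluded) for flag-negative or flag-missing cases. The
#' special name `"status"` contrasts all cases with all controls.
#'
#' @param cohort a [join_cohort()] result.
#' @param phenotype a flag column of `cohort$pheno`, or `"status"`.
#' @return Numeric vector of 1/0/`NA` labels.
#' @export
phenotype_labels <- function(cohort, phenotype) {
  status <- cohort$pheno$status
  if (phenotype == "status") return(as.numeric(status == "case"))
  if (!phenotype %in% names(cohort$pheno))
    stop("unknown phenotype flag: ", phenotype)
  flag <- cohort$pheno[[phenotype]]
  labels <- rep(NA_real_, length(status))
  labels[status == "control"] <- 0
  labels[status == "case" & !is.na(flag) & flag == 1] <- 1
  labels
}

#' Per-variant case-control allelic association for one phenotype
#'
#' For each variant: the allelic chi-squared with OR and Woolf CI
#' (autosomes, pooled sexes), a sex-adjusted logistic OR, and the
#' Breslow-Day homogeneity P across sex strata. X-chromosome variants are
#' never pooled across sexes: per-sex allele tables (males contribute one
#' allele) are combined by Cochran-Mantel-Haenszel, and the reported OR/CI
#' is the MH common OR.
#'
#' @param cohort a [join_cohort()] result, QC applied.
#' @param phenotype contrast name (see [phenotype_labels()]).
#' @param min_events minimum number of phenotype-positive samples
#'   (default 5); fewer is an error.
#' @param interaction also test a dose x sex interaction?
#' @param bd_alpha significance threshold annotated on the Breslow-Day
#'   column (default 0.02).
#' @return data.frame of class `"assoc_result"`, one row per variant, with
#'   `emp1`/`emp2` columns left `NA` for [empirical_p()] to fill.
#' @export
run_association <- function(cohort, phenotype, min_events = 5,
                            interaction = FALSE, bd_alpha = 0.02) {
  labels <- phenotype_labels(cohort, phenotype)
  n_events <- sum(labels == 1, na.rm = TRUE)
  if (n_events < min_events)
    stop("phenotype '", phenotype, "' has ", n_events,
         " events; fewer than ", min_events, " are not tested")
  g <- cohort$g
  sex <- g$sex
  m <- nrow(g$variants)
  out <- data.frame(
    id = g$variants$id, phenotype = phenotype, n_events = n_events,
    chrom = g$variants$chrom,
    or_ = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    chi2 = NA_real_, p_asymptotic = NA_real_,
    or_adjusted = NA_real_, p_adjusted = NA_real_,
    p_interaction = NA_real_,
    p_bd = NA_real_, bd_flag = NA, haldane = NA,
    emp1 = NA_real_, emp2 = NA_real_,
    stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    d <- g$dose[, j]
    on_x <- g$variants$chrom[j] == "X"
    strata <- list()
    for (s in c("male", "female")) {
      sel <- sex == s
      if (sum(sel & !is.na(d) & !is.na(labels)) == 0) next
      tb <- try(allele_table(d[sel], labels[sel], on_x = on_x,
                             sex = sex[sel]), silent = TRUE)
      if (!inherits(tb, "try-error")) strata[[s]] <- tb
    }
    if (on_x) {
      res <- try(cmh_assoc(strata), silent = TRUE)
      if (!inherits(res, "try-error")) {
        out$or_[j] <- res$or; out$ci_low[j] <- res$ci_low
        out$ci_high[j] <- res$ci_high
        out$chi2[j] <- res$chi2; out$p_asymptotic[j] <- res$p
        out$haldane[j] <- FALSE
      }
    } else {
      tb <- allele_table(d, labels)
      ct <- try(allelic_chi2(tb), silent = TRUE)
      if (!inherits(ct, "try-error")) {
        out$chi2[j] <- ct$chi2; out$p_asymptotic[j] <- ct$p
      }
      orci <- odds_ratio_ci(tb)
      out$or_[j] <- orci$or; out$ci_low[j] <- orci$ci_low
      out$ci_high[j] <- orci$ci_high; out$haldane[j] <- orci$haldane
    }
    la <- try(logistic_assoc(d, labels, sex = sex,
                             interaction = interaction), silent = TRUE)
    if (!inherits(la, "try-error")) {
      out$or_adjusted[j] <- la$or_adjusted
      out$p_adjusted[j] <- la$p_adjusted
      out$p_interaction[j] <- la$p_interaction
    }
    bd <- try(suppressWarnings(breslow_day(strata)), silent = TRUE)
    if (!inherits(bd, "try-error")) {
      out$p_bd[j] <- bd$p_bd
      out$bd_flag[j] <- bd$p_bd < bd_alpha
    }
  }
  class(out) <- c("assoc_result", "data.frame")
  out
}
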