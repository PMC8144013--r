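#' Effect-allele frequency and minor allele frequency
#'
#' @param doses numeric vector of per-sample effect-allele counts
#'   (0/1/2, `NA` missing).
#' @return List with `eaf` (unfolded effect-allele frequency) and `maf`
#'   (folded to at most 0.5).
#' @export
compute_maf <- function(doses) {
  n <- sum(!is.na(doses))
  if (n == 0) stop("all doses missing: frequency undefined")
  eaf <- sum(doses, na.rm = TRUE) / (2 * n)
  list(eaf = eaf, maf = min(eaf, 1 - eaf))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditional on the observed allele counts: the P
#' value sums the probabilities of all heterozygote configurations no more
#' probable than the observed one (Wigginton-style recurrence over the
#' conditional distribution of heterozygote counts). Monomorphic variants
#' return P = 1 by convention.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts.
#' @return Exact two-sided P value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0) stop("no genotypes")
  n_a <- 2 * n_hom_alt + n_het        # minor-side allele count
  n_b <- 2 * n_hom_ref + n_het
  if (n_a > n_b) { tmp <- n_a; n_a <- n_b; n_b <- tmp }
  if (n_a == 0) return(1)
  hets <- seq(n_a %% 2, n_a, by = 2)  # feasible heterozygote counts
  # unnormalised conditional probabilities via the standard recurrence:
  # P(h+2)/P(h) = 4 * n_AA(h) * n_BB(h) / ((h+2) * (h+1))
  lp <- numeric(length(hets))
  for (i in seq_along(hets)[-1]) {
    h <- hets[i - 1]
    n_aa <- (n_a - h) / 2
    n_bb <- (n_b - h) / 2
    lp[i] <- lp[i - 1] + log(4 * n_aa * n_bb) - log((h + 2) * (h + 1))
  }
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- which(hets == n_het)
  if (!length(obs))
    stop("heterozygote count ", n_het,
         " infeasible for allele count ", n_a)
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

#' Variant-level quality control
#'
#' Applies the standard pre-association filters: overall call rate,
#' case/control differential missingness, minor allele frequency, and exact
#' Hardy-Weinberg equilibrium evaluated in controls only. All thresholds are
#' strict as stated: a variant is dropped when missingness >= `geno`,
#' |case - control missingness| >= `diff_miss`, MAF <= `maf`, or control
#' HWE P <= `hwe`. On chromosome X, HWE uses female controls only (male
#' hemizygotes carry no heterozygote information) and call rates count all
#' samples.
#'
#' @param cohort a [join_cohort()] result (genotypes + status).
#' @param geno maximum tolerated missing genotype rate (default 0.05).
#' @param diff_miss maximum tolerated absolute case-control missingness
#'   difference (default 0.03).
#' @param maf minimum minor allele frequency, exclusive (default 0.01).
#' @param hwe minimum control HWE exact P, exclusive (default 1e-6).
#' @return List with `cohort` (filtered) and `report` (data.frame of class
#'   `"qc_report"`, one row per input variant).
#' @export
apply_filters <- function(cohort, geno = 0.05, diff_miss = 0.03,
                          maf = 0.01, hwe = 1e-6) {
  g <- cohort$g
  status <- cohort$pheno$status
  is_case <- status == "case"
  is_ctrl <- status == "control"
  m <- nrow(g$variants)

  rep_df <- data.frame(
    id = g$variants$id, chrom = g$variants$chrom,
    call_rate = NA_real_, call_rate_cases = NA_real_,
    call_rate_controls = NA_real_, diff_missingness = NA_real_,
    maf_all = NA_real_, maf_cases = NA_real_, maf_controls = NA_real_,
    hwe_p_controls = NA_real_, pass = TRUE, reasons = "",
    stringsAsFactors = FALSE)

  for (j in seq_len(m)) {
    d <- g$dose[, j]
    cr <- mean(!is.na(d))
    cr_ca <- mean(!is.na(d[is_case]))
    cr_co <- mean(!is.na(d[is_ctrl]))
    rep_df$call_rate[j] <- cr
    rep_df$call_rate_cases[j] <- cr_ca
    rep_df$call_rate_controls[j] <- cr_co
    dm <- abs((1 - cr_ca) - (1 - cr_co))
    rep_df$diff_missingness[j] <- dm
    rep_df$maf_all[j] <- if (any(!is.na(d))) compute_maf(d)$maf else NA
    rep_df$maf_cases[j] <-
      if (any(!is.na(d[is_case]))) compute_maf(d[is_case])$maf else NA
    rep_df$maf_controls[j] <-
      if (any(!is.na(d[is_ctrl]))) compute_maf(d[is_ctrl])$maf else NA

    on_x <- g$variants$chrom[j] == "X"
    hwe_idx <- if (on_x) is_ctrl & g$sex == "female" else is_ctrl
    dh <- d[hwe_idx]
    dh <- dh[!is.na(dh)]
    rep_df$hwe_p_controls[j] <- if (length(dh)) {
      hwe_exact_test(sum(dh == 0), sum(dh == 1), sum(dh == 2))
    } else NA_real_

    reasons <- character(0)
    if ((1 - cr) >= geno) reasons <- c(reasons, "call_rate")
    if (!is.na(dm) && dm >= diff_miss) reasons <- c(reasons, "diff_miss")
    if (is.na(rep_df$maf_all[j]) || rep_df$maf_all[j] <= maf)
      reasons <- c(reasons, "maf")
    if (!is.na(rep_df$hwe_p_controls[j]) &&
        rep_df$hwe_p_controls[j] <= hwe)
      reasons <- c(reasons, "hwe")
    rep_df$pass[j] <- length(reasons) == 0
    rep_df$reasons[j] <- paste(reasons, collapse = ";")
  }
  class(rep_df) <- c("qc_report", "data.frame")

  keep <- which(rep_df$pass)
  if (!length(keep)) warning("no variants pass quality control")
  g$dose <- g$dose[, keep, drop = FALSE]
  g$variants <- g$variants[keep, , drop = FALSE]
  rownames(g$variants) <- NULL
  cohort$g <- g
  list(cohort = cohort, report = rep_df)
}

#' Write a QC report as TSV
#' @param report a `"qc_report"` data.frame from [apply_filters()].
#' @param path output path.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
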