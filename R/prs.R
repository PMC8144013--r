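#' Composite LD between two variants
#'
#' Squared Pearson correlation of unphased dose vectors (composite LD),
#' computed over samples with both doses non-missing. A zero-variance
#' vector yields r-squared 0 with a warning (no LD information).
#'
#' @param doses_v,doses_w numeric dose vectors.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(doses_v, doses_w) {
  keep <- !is.na(doses_v) & !is.na(doses_w)
  if (sum(keep) < 2) stop("need >= 2 samples with both doses non-missing")
  v <- doses_v[keep]; w <- doses_w[keep]
  if (stats::var(v) == 0 || stats::var(w) == 0) {
    warning("zero dose variance: r^2 defined as 0")
    return(0)
  }
  stats::cor(v, w)^2
}

#' Clumping configuration
#'
#' @param window_kb half-window in kilobases around each index SNP
#'   (default 250).
#' @param r2_max LD threshold above which a neighbour is removed
#'   (default 0.2).
#' @param mhc_exclude chromosome-6 long-range-LD interval removed before
#'   clumping, in basepairs (default 29,700,000-33,300,000).
#' @return List of class `"clump_config"`.
#' @export
clump_config <- function(window_kb = 250, r2_max = 0.2,
                         mhc_exclude = c(29700000, 33300000)) {
  stopifnot(window_kb > 0, r2_max > 0, r2_max < 1)
  structure(list(window_kb = window_kb, r2_max = r2_max,
                 mhc_exclude = mhc_exclude), class = "clump_config")
}

#' Greedy P-value clumping of summary statistics
#'
#' MHC-interval variants are removed first. Variants are then visited by
#' ascending P (ties broken by chromosome then position); each unclaimed
#' visit becomes an index SNP and claims every unclaimed variant within
#' `window_kb` kilobases on the same chromosome whose LD with it exceeds
#' `r2_max`. The retained set is the index SNPs.
#'
#' @param stats_df summary statistics (see [read_sumstats()]); variants
#'   absent from `ref` are dropped with a message.
#' @param ref LD reference genotypes (a [genotype_matrix()]); the analysis
#'   cohort's own genotypes by default of the surrounding pipeline.
#' @param cfg a [clump_config()].
#' @return Character vector of retained variant ids.
#' @export
clump <- function(stats_df, ref, cfg = clump_config()) {
  in_ref <- stats_df$id %in% ref$variants$id
  if (any(!in_ref))
    message(sum(!in_ref), " summary-statistic variant(s) absent from the ",
            "LD reference dropped")
  s <- stats_df[in_ref, , drop = FALSE]
  in_mhc <- s$chrom == "6" &
    s$pos >= cfg$mhc_exclude[1] & s$pos <= cfg$mhc_exclude[2]
  s <- s[!in_mhc, , drop = FALSE]
  if (!nrow(s)) return(character(0))
  s <- s[order(s$p, s$chrom, s$pos), , drop = FALSE]
  window_bp <- cfg$window_kb * 1000
  dose_of <- function(id) ref$dose[, match(id, ref$variants$id)]
  claimed <- rep(FALSE, nrow(s))
  retained <- character(0)
  for (i in seq_len(nrow(s))) {
    if (claimed[i]) next
    claimed[i] <- TRUE
    retained <- c(retained, s$id[i])
    near <- which(!claimed & s$chrom == s$chrom[i] &
                    abs(s$pos - s$pos[i]) <= window_bp)
    if (!length(near)) next
    di <- dose_of(s$id[i])
    r2 <- vapply(near, function(j)
      suppressWarnings(ld_r2(di, dose_of(s$id[j]))), numeric(1))
    claimed[near[r2 > cfg$r2_max]] <- TRUE
  }
  retained
}

#' Polygenic risk score at one P-value threshold
#'
#' `score = sum over retained variants with p < threshold of dose * beta`.
#' Missing doses are imputed as twice the cohort effect-allele frequency
#' (mean imputation) so scores remain comparable across samples; the count
#' of imputed doses is attached as an attribute.
#'
#' @param g a [genotype_matrix()] with doses aligned to the summary
#'   statistics' effect alleles.
#' @param stats_df summary statistics.
#' @param retained ids from [clump()].
#' @param threshold include variants with `p < threshold` (strict).
#' @return Named numeric vector of per-sample scores; attributes `n_snps`
#'   and `n_imputed`.
#' @export
prs_score <- function(g, stats_df, retained, threshold) {
  use <- stats_df$id %in% retained & stats_df$p < threshold
  ids <- stats_df$id[use]
  beta <- stats_df$beta[use]
  if (!length(ids)) {
    warning("no variants pass threshold ", threshold, "; scores are 0")
    out <- stats::setNames(rep(0, length(g$samples)), g$samples)
    attr(out, "n_snps") <- 0L
    attr(out, "n_imputed") <- 0L
    return(out)
  }
  idx <- match(ids, g$variants$id)
  if (anyNA(idx))
    stop("retained variants absent from genotypes: ",
         paste(ids[is.na(idx)], collapse = ", "))
  D <- g$dose[, idx, drop = FALSE]
  n_imputed <- sum(is.na(D))
  if (n_imputed) {
    eaf2 <- colMeans(D, na.rm = TRUE)  # mean dose = 2 * effect-allele freq
    for (j in seq_along(idx)) D[is.na(D[, j]), j] <- eaf2[j]
  }
  out <- stats::setNames(as.vector(D %*% beta), g$samples)
  attr(out, "n_snps") <- length(ids)
  attr(out, "n_imputed") <- n_imputed
  out
}

# Nagelkerke pseudo-R^2 of a fitted binomial glm.
nagelkerke_r2 <- function(fit) {
  n <- length(fit$y)
  r2_cs <- 1 - exp((fit$deviance - fit$null.deviance) / n)
  r2_max <- 1 - exp(-fit$null.deviance / n)
  if (r2_max <= 0) return(0)
  r2_cs / r2_max
}

fit_score_model <- function(y, score, covars) {
  df <- data.frame(y = y, score = score)
  df <- cbind(df, covars)
  full <- suppressWarnings(
    stats::glm(y ~ ., family = stats::binomial(), data = df))
  null <- suppressWarnings(
    stats::glm(y ~ . - score, family = stats::binomial(), data = df))
  co <- summary(full)$coefficients
  p <- if ("score" %in% rownames(co)) co["score", 4] else NA_real_
  list(p = p,
       r2_delta = max(0, nagelkerke_r2(full) - nagelkerke_r2(null)),
       converged = full$converged)
}

#' Threshold ladder fit of the polygenic score with permutation best-fit P
#'
#' For each P-value threshold, fits `logit(phenotype) ~ score + covariates`
#' and the covariate-only model, reporting the score's Wald P and the
#' Nagelkerke pseudo-R-squared difference. The best fit is the threshold
#' with the smallest P; its family-wise empirical P is obtained by
#' permuting the phenotype labels (covariates stay attached to samples),
#' re-selecting the best threshold in every permutation, and counting
#' permutations whose best P is at least as small:
#' `emp_p = (1 + #\{min_t P_perm <= min_t P_obs\}) / (R + 1)`.
#'
#' @param scores named list (or matrix) of per-sample score vectors, one
#'   per threshold; names are the threshold labels.
#' @param labels binary phenotype (case-only sub-phenotype flags in the
#'   intended use); `NA` excluded.
#' @param covars data.frame of covariates (e.g. age, sex) aligned with the
#'   samples.
#' @param plan a [permutation_plan()] for the best-fit correction.
#' @return List: `fits` (data.frame: threshold, n_snps, r2_delta, p),
#'   `best` (row name of the best threshold), `emp_p`.
#' @export
prs_fit <- function(scores, labels, covars, plan = permutation_plan()) {
  if (is.matrix(scores))
    scores <- lapply(seq_len(ncol(scores)),
                     function(j) scores[, j]) |>
      stats::setNames(colnames(scores))
  keep <- !is.na(labels)
  for (v in seq_along(covars)) keep <- keep & !is.na(covars[[v]])
  y <- labels[keep]
  if (all(y == 0) || all(y == 1))
    stop("phenotype is constant: cannot fit")
  covars <- covars[keep, , drop = FALSE]
  n_snps <- vapply(scores, function(s)
    as.integer(attr(s, "n_snps") %||% NA_integer_), integer(1))
  scores <- lapply(scores, function(s) s[keep])

  fits <- do.call(rbind, lapply(names(scores), function(th) {
    f <- fit_score_model(y, scores[[th]], covars)
    data.frame(threshold = th,
               n_snps = n_snps[[th]],
               r2_delta = f$r2_delta, p = f$p, converged = f$converged,
               stringsAsFactors = FALSE)
  }))
  best_i <- which.min(fits$p)
  obs_best <- fits$p[best_i]

  set.seed(plan$seed)
  cnt <- 0
  for (r in seq_len(plan$n_perm)) {
    yp <- sample(y)
    pmin_r <- min(vapply(scores, function(s)
      fit_score_model(yp, s, covars)$p, numeric(1)), na.rm = TRUE)
    if (pmin_r <= obs_best + 1e-12) cnt <- cnt + 1
  }
  list(fits = fits, best = fits$threshold[best_i],
       emp_p = (1 + cnt) / (plan$n_perm + 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scores across the standard threshold ladder
#'
#' Convenience wrapper: clump once, then score at each threshold of the a
#' priori ladder (0.001, 0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5 by default).
#'
#' @param g aligned genotypes.
#' @param stats_df summary statistics.
#' @param cfg a [clump_config()].
#' @param thresholds numeric ladder.
#' @return Named list of score vectors (one per threshold), with the
#'   retained-id vector as attribute `retained`.
#' @export
prs_ladder <- function(g, stats_df, cfg = clump_config(),
                       thresholds = c(0.001, 0.01, 0.05, 0.1,
                                      0.2, 0.3, 0.4, 0.5)) {
  retained <- clump(stats_df, g, cfg)
  out <- lapply(thresholds, function(th)
    suppressWarnings(prs_score(g, stats_df, retained, th)))
  names(out) <- as.character(thresholds)
  attr(out, "retained") <- retained
  out
}
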