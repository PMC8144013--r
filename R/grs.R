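#' Weighted genetic risk score per sample
#'
#' Each risk allele contributes its weight beta = ln(OR); the per-sample
#' score is the weighted allele sum divided by the total number of scored
#' alleles, i.e. `sum(dose_v * beta_v) / (2 * n_used)` where `n_used`
#' counts the sample's non-missing variants. Missing variants are excluded
#' from numerator and denominator, so the score is an average per scored
#' allele and stays comparable across samples with different call rates.
#'
#' @param g a [genotype_matrix()] with doses aligned to the weight table's
#'   effect alleles (see [align_to_effect_allele()]).
#' @param w weight table (`id`, `effect_allele`, `beta`).
#' @return data.frame of class `"grs_profile"`: `sample_id`, `score`,
#'   `n_used`; `tertile` is added by [assign_tertiles()].
#' @export
wgrs <- function(g, w) {
  idx <- match(w$id, g$variants$id)
  if (anyNA(idx))
    stop("weight-table variants absent from genotypes: ",
         paste(w$id[is.na(idx)], collapse = ", "))
  mismatch <- w$effect_allele != g$variants$allele_a[idx]
  if (any(mismatch))
    stop("doses not aligned to effect alleles for: ",
         paste(w$id[mismatch], collapse = ", "),
         " (run align_to_effect_allele first)")
  D <- g$dose[, idx, drop = FALSE]
  M <- !is.na(D)
  n_used <- rowSums(M)
  if (any(n_used == 0))
    stop("sample(s) with no scored variants: ",
         paste(g$samples[n_used == 0], collapse = ", "))
  D0 <- ifelse(M, D, 0)
  score <- as.vector(D0 %*% w$beta) / (2 * n_used)
  structure(data.frame(sample_id = g$samples, score = score,
                       n_used = n_used, stringsAsFactors = FALSE),
            class = c("grs_profile", "data.frame"))
}

#' Tertile cutpoints from the control score distribution
#'
#' Cutpoints sit at the 33 1/3 and 66 2/3 percentiles of the control
#' scores, computed with the linear-interpolation quantile (type 7). Risk
#' categories are then defined for everyone — cases included — from these
#' control-derived cutpoints, never from the pooled or case distribution.
#'
#' @param control_scores numeric vector of control wGRS values (>= 3).
#' @return Named numeric `c(t1, t2)`.
#' @export
control_tertiles <- function(control_scores) {
  control_scores <- control_scores[!is.na(control_scores)]
  if (length(control_scores) < 3)
    stop("need at least 3 control scores for tertiles")
  q <- stats::quantile(control_scores, probs = c(1, 2) / 3,
                       type = 7, names = FALSE)
  if (q[1] == q[2])
    warning("degenerate control distribution: tertile cutpoints coincide")
  c(t1 = q[1], t2 = q[2])
}

#' Assign low/medium/high risk categories from control cutpoints
#'
#' Left-closed rule: `low` if score <= t1, `medium` if t1 < score <= t2,
#' `high` otherwise.
#'
#' @param profiles a [wgrs()] result.
#' @param cutpoints output of [control_tertiles()].
#' @return `profiles` with a `tertile` factor column (low < medium < high).
#' @export
assign_tertiles <- function(profiles, cutpoints) {
  s <- profiles$score
  tert <- ifelse(s <= cutpoints[["t1"]], "low",
                 ifelse(s <= cutpoints[["t2"]], "medium", "high"))
  profiles$tertile <- factor(tert, levels = c("low", "medium", "high"))
  profiles
}

#' Tertile-versus-reference logistic odds ratios
#'
#' Fits `label ~ medium + high + sex` (binomial, logit) with the low
#' tertile as reference and reports OR, Wald 95% CI and P for the medium
#' and high indicators. Analyses with fewer than `min_ref_events`
#' phenotype-positive samples in the reference tertile are skipped with a
#' reason rather than reported.
#'
#' @param profiles a [wgrs()] result with tertiles assigned.
#' @param labels binary phenotype vector aligned with `profiles`
#'   (`NA` excluded).
#' @param sex optional per-sample covariate.
#' @param min_ref_events minimum events in the low tertile (default 5).
#' @param level confidence level.
#' @return data.frame with rows `medium` and `high`: `or`, `ci_low`,
#'   `ci_high`, `p`, `n_events`; or a `"skipped"` result carrying the
#'   reason.
#' @export
tertile_assoc <- function(profiles, labels, sex = NULL,
                          min_ref_events = 5, level = 0.95) {
  stopifnot(length(labels) == nrow(profiles))
  keep <- !is.na(labels) & !is.na(profiles$tertile)
  tert <- profiles$tertile[keep]
  y <- labels[keep]
  ref_events <- sum(y == 1 & tert == "low")
  if (ref_events < min_ref_events) {
    return(structure(list(skipped = TRUE,
                          reason = sprintf(
                            "%d event(s) in reference tertile (< %d)",
                            ref_events, min_ref_events)),
                     class = "tertile_assoc_skipped"))
  }
  df <- data.frame(y = y, tertile = tert)
  use_sex <- !is.null(sex)
  if (use_sex) {
    df$sex <- factor(sex[keep])
    if (nlevels(droplevels(df$sex)) < 2) use_sex <- FALSE
  }
  form <- if (use_sex) y ~ tertile + sex else y ~ tertile
  fit <- stats::glm(form, family = stats::binomial(), data = df)
  co <- summary(fit)$coefficients
  z <- stats::qnorm(1 - (1 - level) / 2)
  rows <- c(medium = "tertilemedium", high = "tertilehigh")
  out <- do.call(rbind, lapply(names(rows), function(nm) {
    b <- co[rows[[nm]], 1]; se <- co[rows[[nm]], 2]
    data.frame(tertile = nm, or = exp(b),
               ci_low = exp(b - z * se), ci_high = exp(b + z * se),
               p = co[rows[[nm]], 4],
               n_events = sum(y == 1 & tert == nm),
               stringsAsFactors = FALSE)
  }))
  out$ref_events <- ref_events
  rownames(out) <- NULL
  out
}
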