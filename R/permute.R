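#' Describe a permutation run
#'
#' @param n_perm number of label permutations (default 10000).
#' @param seed integer seed; all permutation randomness flows from it.
#' @param strata optional per-sample stratum labels (e.g. sex); labels are
#'   then shuffled within strata only, preserving the stratum margins.
#' @param exhaustive enumerate every distinct label assignment instead of
#'   sampling (feasible for toy cohorts only; unstratified).
#' @return List of class `"permutation_plan"`.
#' @export
permutation_plan <- function(n_perm = 10000, seed = 1, strata = NULL,
                             exhaustive = FALSE) {
  stopifnot(n_perm >= 1)
  structure(list(n_perm = as.integer(n_perm), seed = as.integer(seed),
                 strata = strata, exhaustive = exhaustive),
            class = "permutation_plan")
}

# Per-sample allele contribution (C) and allele-count (W) matrices, with
# missing doses zeroed: a = crossprod(C, labels), alleles = crossprod(W,
# labels). On X, males contribute one allele (dose/2).
allele_contrib <- function(g) {
  D <- g$dose
  M <- !is.na(D)
  C <- ifelse(M, D, 0)
  W <- matrix(2, nrow(D), ncol(D))
  on_x <- g$variants$chrom == "X"
  if (any(on_x)) {
    male <- g$sex == "male"
    if (any(male)) {
      C[male, on_x] <- C[male, on_x] / 2
      W[male, on_x] <- 1
    }
  }
  W[!M] <- 0
  list(C = C, W = W)
}

# Vectorised allelic chi-squared for a matrix of label vectors.
# Returns an m x R matrix; tables with a zero margin score 0.
chi2_for_labels <- function(C, W, L, tot_a, tot_alleles) {
  a <- crossprod(C, L)
  n1 <- crossprod(W, L)
  b <- n1 - a
  cc <- tot_a - a
  d <- (tot_alleles - n1) - cc
  n <- tot_alleles
  den <- (a + b) * (cc + d) * (a + cc) * (b + d)
  chi2 <- n * (a * d - b * cc)^2 / den
  chi2[den <= 0] <- 0
  chi2
}

#' Pointwise (EMP1) and family-wise max(T) (EMP2) empirical P values
#'
#' Shuffles the phenotype labels of the analysed contrast (within strata if
#' the plan gives any), recomputes the allelic chi-squared for every family
#' variant under each permutation, and reports
#' `emp1 = (1 + #\{T_perm >= T_obs\}) / (R + 1)` per variant and
#' `emp2 = (1 + #\{max_family T_perm >= T_obs\}) / (R + 1)`, the max(T)
#' family-wise-corrected P. Permutations where a variant's table has a zero
#' margin score 0 for that variant; the tally is reported. With
#' `exhaustive = TRUE` every distinct assignment is enumerated and the
#' estimator drops the +1 (the observed assignment is in the enumeration).
#'
#' @param cohort a [join_cohort()] result (QC applied).
#' @param phenotype contrast name (see [phenotype_labels()]).
#' @param plan a [permutation_plan()].
#' @param family variant ids over which max(T) is taken; default all
#'   variants in the cohort.
#' @return data.frame: `id`, `stat` (observed chi-squared), `emp1`,
#'   `emp2`; attribute `n_undefined` counts zero-margin permuted
#'   statistics.
#' @export
empirical_p <- function(cohort, phenotype, plan = permutation_plan(),
                        family = NULL) {
  g <- cohort$g
  if (is.null(family)) family <- g$variants$id
  if (!length(family)) stop("empty variant family")
  keep_v <- match(family, g$variants$id)
  if (anyNA(keep_v))
    stop("family variants absent from cohort: ",
         paste(family[is.na(keep_v)], collapse = ", "))
  labels <- phenotype_labels(cohort, phenotype)
  use <- !is.na(labels)
  gs <- g
  gs$dose <- g$dose[use, keep_v, drop = FALSE]
  gs$sex <- g$sex[use]
  gs$variants <- g$variants[keep_v, , drop = FALSE]
  l0 <- labels[use]
  cw <- allele_contrib(gs)
  tot_a <- colSums(cw$C)
  tot_alleles <- colSums(cw$W)
  obs <- chi2_for_labels(cw$C, cw$W, matrix(l0, ncol = 1),
                         tot_a, tot_alleles)[, 1]

  n <- length(l0)
  strata <- if (is.null(plan$strata)) rep(1L, n) else {
    s <- plan$strata[use]
    if (length(s) != n) stop("strata must cover every analysed sample")
    s
  }
  stratum_idx <- split(seq_len(n), strata)

  if (plan$exhaustive) {
    if (!is.null(plan$strata))
      stop("exhaustive enumeration is unstratified only")
    k <- sum(l0 == 1)
    combos <- utils::combn(n, k)
    L <- matrix(0, n, ncol(combos))
    L[cbind(as.vector(combos),
            rep(seq_len(ncol(combos)), each = k))] <- 1
    perm_chi2 <- chi2_for_labels(cw$C, cw$W, L, tot_a, tot_alleles)
    R <- ncol(L)
    ge <- perm_chi2 >= obs - 1e-12
    maxs <- apply(perm_chi2, 2, max)
    emp1 <- rowSums(ge) / R
    emp2 <- vapply(obs, function(t0) mean(maxs >= t0 - 1e-12), numeric(1))
    n_undef <- sum(perm_chi2 == 0 & tot_a > 0)
  } else {
    set.seed(plan$seed)
    R <- plan$n_perm
    chunk <- 2000L
    cnt1 <- numeric(length(obs))
    cnt_max <- numeric(length(obs))
    n_undef <- 0
    done <- 0L
    while (done < R) {
      nr <- min(chunk, R - done)
      L <- matrix(0, n, nr)
      for (r in seq_len(nr)) {
        lp <- numeric(n)
        for (idx in stratum_idx) lp[idx] <- sample(l0[idx])
        L[, r] <- lp
      }
      perm_chi2 <- chi2_for_labels(cw$C, cw$W, L, tot_a, tot_alleles)
      cnt1 <- cnt1 + rowSums(perm_chi2 >= obs - 1e-12)
      maxs <- apply(perm_chi2, 2, max)
      cnt_max <- cnt_max +
        vapply(obs, function(t0) sum(maxs >= t0 - 1e-12), numeric(1))
      n_undef <- n_undef + sum(perm_chi2 == 0)
      done <- done + nr
    }
    emp1 <- (1 + cnt1) / (R + 1)
    emp2 <- (1 + cnt_max) / (R + 1)
  }
  out <- data.frame(id = gs$variants$id, stat = obs,
                    emp1 = emp1, emp2 = emp2, stringsAsFactors = FALSE)
  attr(out, "n_undefined") <- n_undef
  out
}

#' Append empirical P values to an association result
#'
#' @param assoc an `"assoc_result"` from [run_association()].
#' @param emp an [empirical_p()] result for the same phenotype/family.
#' @return `assoc` with `emp1`/`emp2` filled for matching variants.
#' @export
add_empirical_p <- function(assoc, emp) {
  i <- match(assoc$id, emp$id)
  assoc$emp1 <- emp$emp1[i]
  assoc$emp2 <- emp$emp2[i]
  assoc
}
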