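#' Summarise a phenotype table
#'
#' Per-flag counts among cases with missing-aware denominators: a flag
#' observed for only part of the cohort (e.g. mucosal morphology) is
#' summarised over its non-missing subset. The `female` row summarises sex
#' among all cases.
#'
#' @param pheno a phenotype data.frame (see [join_cohort()]).
#' @return data.frame: `item`, `n`, `denominator`, `pct`.
#' @export
pheno_summary <- function(pheno) {
  cases <- pheno[pheno$status == "case", , drop = FALSE]
  skip <- c("sample_id", "status", "sex", "age", "age_at_diagnosis")
  flags <- setdiff(names(pheno), skip)
  rows <- list(data.frame(item = "female",
                          n = sum(cases$sex == "female"),
                          denominator = nrow(cases),
                          stringsAsFactors = FALSE))
  for (fl in flags) {
    v <- cases[[fl]]
    rows[[length(rows) + 1]] <-
      data.frame(item = fl, n = sum(v == 1, na.rm = TRUE),
                 denominator = sum(!is.na(v)), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$pct <- 100 * out$n / out$denominator
  out
}

#' Human-readable association / risk-score report
#'
#' Emits the familiar results layout: a per-variant block (variant,
#' alleles, MAF in all/cases/controls, OR with CI, family-wise empirical
#' P) filtered at an EMP2 cutoff, and a tertile odds-ratio block when a
#' [tertile_assoc()] table is supplied.
#'
#' @param assoc an `"assoc_result"` (with `emp2` filled) or NULL.
#' @param qc optional `"qc_report"` supplying the MAF columns.
#' @param grs optional [tertile_assoc()] table (or named list of them).
#' @param emp2_cutoff report variants with `emp2 <=` this (default 0.05).
#' @param file optional path; lines are also returned invisibly.
#' @return Character vector of report lines, invisibly.
#' @export
report <- function(assoc = NULL, qc = NULL, grs = NULL,
                   emp2_cutoff = 0.05, file = NULL) {
  lines <- character(0)
  if (!is.null(assoc)) {
    lines <- c(lines,
               sprintf("Variant associations (EMP2 <= %g)", emp2_cutoff),
               paste("variant", "phenotype", "MAF_all", "MAF_cases",
                     "MAF_controls", "OR (95% CI)", "EMP2", sep = "\t"))
    sel <- !is.na(assoc$emp2) & assoc$emp2 <= emp2_cutoff
    shown <- assoc[sel, , drop = FALSE]
    for (i in seq_len(nrow(shown))) {
      mafs <- c(NA, NA, NA)
      if (!is.null(qc)) {
        qi <- match(shown$id[i], qc$id)
        mafs <- c(qc$maf_all[qi], qc$maf_cases[qi], qc$maf_controls[qi])
      }
      lines <- c(lines, sprintf(
        "%s\t%s\t%s\t%s\t%s\t%.2f (%.2f-%.2f)\t%.4g",
        shown$id[i], shown$phenotype[i],
        ifelse(is.na(mafs[1]), "-", sprintf("%.2f", mafs[1])),
        ifelse(is.na(mafs[2]), "-", sprintf("%.2f", mafs[2])),
        ifelse(is.na(mafs[3]), "-", sprintf("%.2f", mafs[3])),
        shown$or_[i], shown$ci_low[i], shown$ci_high[i], shown$emp2[i]))
    }
  }
  if (!is.null(grs)) {
    if (is.data.frame(grs)) grs <- list(phenotype = grs)
    for (nm in names(grs)) {
      tab <- grs[[nm]]
      lines <- c(lines, "", sprintf("wGRS tertiles: %s", nm),
                 "tertile\tOR [95% CI]\tP")
      if (inherits(tab, "tertile_assoc_skipped")) {
        lines <- c(lines, paste0("skipped: ", tab$reason))
      } else {
        lines <- c(lines, "low\treference\t-")
        for (i in seq_len(nrow(tab)))
          lines <- c(lines, sprintf("%s\t%.2f [%.2f-%.2f]\t%.3f",
                                    tab$tertile[i], tab$or[i],
                                    tab$ci_low[i], tab$ci_high[i],
                                    tab$p[i]))
      }
    }
  }
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run byte-identically: package
#' version, root seed, input-file MD5 digests, and the convention flags
#' that affect numbers (quantile method, X-chromosome male coding, CI
#' method).
#'
#' @param path output file.
#' @param seed root seed of the run.
#' @param inputs character vector of input file paths (digested).
#' @param extra optional named character vector of additional entries.
#' @return `path`, invisibly.
#' @export
run_manifest <- function(path, seed, inputs = character(0),
                         extra = character(0)) {
  lines <- c(
    paste0("tool\tcdgps ",
           as.character(utils::packageVersion("cdgps"))),
    paste0("seed\t", seed),
    "x_male_coding\t0/2",
    "quantile_method\tlinear-interpolation (type 7)",
    "ci_method\tWoolf (log-scale Wald)",
    "hwe_test\texact (conditional, two-sided)")
  for (f in inputs)
    lines <- c(lines, paste0("input\t", f, "\tmd5:",
                             unname(tools::md5sum(f))))
  if (length(extra))
    lines <- c(lines, paste0(names(extra), "\t", extra))
  writeLines(lines, path)
  invisible(path)
}
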