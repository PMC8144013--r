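#!/usr/bin/env Rscript
# Reconstruct the published per-variant odds ratios from printed minor
# allele frequencies, and the clinical-summary percentages from the
# study-shaped phenotype table.
#
# The printed case/control MAFs and group sizes determine the 2x2 allele
# table up to rounding (counts = round(2n * MAF)), so the crude allelic
# OR and its Woolf CI can be recomputed exactly from the publication
# surface alone. Two rows with very different sample sizes are used.

library(cdgps)

dir.create("results", showWarnings = FALSE)

rows <- data.frame(
  variant = c("rs653178", "rs13098911"),
  phenotype = c("diagnosed_gt7", "antibody_negative"),
  n_cases = c(573, 19), maf_cases = c(0.47, 0.34),
  n_controls = c(1817, 1817), maf_controls = c(0.41, 0.14))

out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
  r <- rows[i, ]
  a <- round(2 * r$n_cases * r$maf_cases)
  cc <- round(2 * r$n_controls * r$maf_controls)
  t <- structure(c(a = a, b = 2 * r$n_cases - a,
                   c = cc, d = 2 * r$n_controls - cc),
                 class = "allele_table")
  orci <- odds_ratio_ci(t)
  chi <- allelic_chi2(t)
  cbind(r, data.frame(a = a, or = round(orci$or, 2),
                      ci_low = round(orci$ci_low, 2),
                      ci_high = round(orci$ci_high, 2),
                      chi2 = round(chi$chi2, 2),
                      p = signif(chi$p, 3)))
}))
write.table(out, "results/table2_reconstruction.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Reconstructed allelic ORs:\n")
print(out[, c("variant", "phenotype", "or", "ci_low", "ci_high")])
cat("\nBoth rows reproduce the published OR (95% CI) at 2 d.p.:\n",
    "rs653178 1.28 (1.12-1.46), rs13098911 3.19 (1.62-6.28)\n\n")

s <- pheno_summary(study_phenotype_table())
write.table(s, "results/pheno_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Clinical summary of the study-shaped cohort (cases):\n")
print(transform(s, pct = round(pct, 1)), row.names = FALSE)
cat("\nKey margins: female", s$n[s$item == "female"], "/ 625 (",
    round(s$pct[s$item == "female"]), "%), TVA/SVA",
    s$n[s$item == "tva_sva"], "/ 546 (",
    round(s$pct[s$item == "tva_sva"]), "%)\n")
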