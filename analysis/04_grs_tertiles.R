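#!/usr/bin/env Rscript
# Weighted genetic risk score over the 39-SNP panel, control-derived
# tertiles, and tertile-versus-reference odds ratios per phenotype.

library(cdgps)

g <- read_genotypes("results/fixtures/signal.tsv", "tsv",
                    variants_file = "results/fixtures/signal.tsv.variants.tsv")
ph <- read.delim("results/fixtures/signal.pheno.tsv")
co <- join_cohort(g, ph)
w <- synthetic_weights()

g_al <- align_to_effect_allele(co$g, w)
prof <- wgrs(g_al, w)
is_ctrl <- co$pheno$status == "control"
cut <- control_tertiles(prof$score[is_ctrl])
prof <- assign_tertiles(prof, cut)
write.table(prof, "results/grs_profiles.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("wGRS: mean %.4f in cases vs %.4f in controls; cutpoints %.4f / %.4f\n",
            mean(prof$score[!is_ctrl]), mean(prof$score[is_ctrl]),
            cut[1], cut[2]))

# disease status and case-only flags against the tertiles
targets <- list(status = as.numeric(co$pheno$status == "case"),
                tva_sva = ifelse(co$pheno$status == "case",
                                 co$pheno$tva_sva, NA),
                anaemia = ifelse(co$pheno$status == "case",
                                 co$pheno$anaemia, NA))
tabs <- list()
for (nm in names(targets)) {
  res <- tertile_assoc(prof, targets[[nm]], sex = co$g$sex)
  tabs[[nm]] <- res
  cat("\nphenotype:", nm, "\n")
  if (inherits(res, "tertile_assoc_skipped")) {
    cat("  skipped:", res$reason, "\n")
  } else {
    print(res, row.names = FALSE)
    out <- cbind(phenotype = nm, res)
    write.table(out, "results/grs_tertile_or.tsv", sep = "\t",
                quote = FALSE, row.names = FALSE,
                append = nm != names(targets)[1],
                col.names = nm == names(targets)[1])
  }
}
writeLines(report(grs = tabs), "results/grs_report.txt")
cat("\nWith synthetic weights on a cohort whose signal sits in two of 39",
    "SNPs, tertile ORs for disease status exceed 1 modestly; case-only",
    "flags track their generating models.\n")
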