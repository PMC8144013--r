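#!/usr/bin/env Rscript
# Clump-and-threshold polygenic risk score on the LD-demo panel:
# P-value clumping (250 kb, r2 0.2, MHC excluded), scoring over the
# a-priori threshold ladder, case-only logistic fits adjusted for age and
# sex, and permutation selection of the best-fit threshold.

library(cdgps)

seed <- 20260926
fxdir <- "results/fixtures"
g <- read_genotypes(file.path(fxdir, "ld-demo.tsv"), "tsv",
                    variants_file = file.path(fxdir,
                                              "ld-demo.tsv.variants.tsv"))
ss <- read_sumstats(file.path(fxdir, "ld-demo.sumstats.tsv"))
cat("summary statistics:", nrow(ss), "variants;",
    "LD reference:", length(g$samples), "samples\n")

ladder <- prs_ladder(g, ss)
retained <- attr(ladder, "retained")
cat("clumping retained", length(retained), "index SNPs",
    "(", nrow(ss) - length(retained), "removed or in the MHC interval )\n")

# synthetic case-only phenotype driven by the mid-ladder score
set.seed(seed)
n <- length(g$samples)
covars <- data.frame(age = runif(n, 1, 79), sex = g$sex)
y <- rbinom(n, 1, plogis(qlogis(0.11) +
                           0.6 * as.vector(scale(ladder[["0.2"]]))))
cat("phenotype prevalence among cases:", round(mean(y), 3), "\n")

fit <- prs_fit(ladder, y, covars,
               permutation_plan(n_perm = 999, seed = seed))
write.table(fit$fits, "results/prs_fits.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nper-threshold fits (bar-plot-ready: threshold, n_snps, r2_delta, p):\n")
print(fit$fits, row.names = FALSE)
cat(sprintf("\nbest-fit threshold P_T = %s (nominal p = %.3g), permutation P_EMP2 = %.4g\n",
            fit$best, fit$fits$p[fit$fits$threshold == fit$best],
            fit$emp_p))
cat("The empirical P corrects the optimism of scanning eight thresholds;",
    "a nominal best-fit p is anti-conservative by construction.\n")
run_manifest("results/prs_manifest.tsv", seed = seed,
             inputs = file.path(fxdir, "ld-demo.sumstats.tsv"),
             extra = c(n_perm = "999",
                       thresholds = paste(fit$fits$threshold,
                                          collapse = ",")))
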