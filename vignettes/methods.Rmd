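---
title: "Genotype-phenotype association, risk scores and permutation inference: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype-phenotype association, risk scores and permutation inference: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdgps)
```

# The problem

Coeliac disease presents very heterogeneously: age at diagnosis, severity
of small-bowel mucosal damage, malabsorption, anaemia, dermatitis
herpetiformis and concomitant autoimmunity all vary between patients with
the same diagnosis. This package implements a complete analysis pipeline
for asking whether established non-HLA susceptibility SNPs — individually,
as a weighted 39-SNP genetic risk score (wGRS39), or as a genome-wide
polygenic risk score (PRS) — are associated with distinct phenotypes in a
case-control cohort (on the order of 625 well-phenotyped cases and 1817
population controls).

Every stage is also exercised on synthetic cohorts with known generating
parameters, so the statistical machinery can be validated without access
to individual-level study data.

# Per-variant association

## Allelic test

For each variant the 2x2 table of effect versus other alleles in
phenotype-positive cases against all population controls is tested with
the Pearson chi-squared statistic on 1 degree of freedom, without
continuity correction (the convention of the standard case-control
toolkits for the allelic test). The odds ratio is `ad/bc` with a Woolf
(log-scale Wald) 95% interval,

$$\exp\left(\ln \widehat{OR} \pm 1.96\sqrt{\tfrac1a+\tfrac1b+\tfrac1c+\tfrac1d}\right),$$

falling back to the Haldane–Anscombe 0.5-correction (flagged) when a cell
is empty. The printed ORs of the source cohort behave exactly like crude
allelic ORs with Woolf intervals: rebuilding the allele counts from
printed group sizes and minor allele frequencies as `round(2n * MAF)`
reproduces, at two decimals, both a large-sample row (OR 1.28,
1.12–1.46) and a 19-case row (OR 3.19, 1.62–6.28). A sex-adjusted
logistic model (`label ~ dose + sex`, additive coding) is reported
alongside the crude OR, never instead of it, with an optional
`dose x sex` interaction term.

## Sex strata and the X chromosome

Homogeneity of the OR between the sexes is tested with the Breslow–Day
statistic around the Mantel–Haenszel common OR (no Tarone adjustment; the
reported default significance threshold is 0.02, i.e. 0.05 Bonferroni-split
over the two strata). X-chromosome male genotypes are hemizygous and
stored on the allele-count scale as 0/2; in allele tables a male
contributes one allele (dose/2) and a female two. Pooled-sex X tests are
deliberately not offered: per-sex tables are combined by
Cochran–Mantel–Haenszel, with the Robins–Breslow–Greenland interval for
the common OR. The 0/2 coding and female-only X Hardy–Weinberg testing
are recorded in every run manifest because the source analysis does not
state its X conventions; they are this package's choices.

## Quality control

Variants are dropped when overall missingness is at least 5%, the
absolute case-control missingness difference is at least 3% (interpreted
as an absolute difference; a test-based criterion would behave
differently only near the boundary), minor allele frequency is at most
1%, or the exact Hardy–Weinberg P in controls is at most 1e-6. Thresholds
are strict as printed ("<5%" keeps 4.99%). The HWE test is the exact
conditional test (summing probabilities of heterozygote configurations no
more probable than observed) rather than the chi-squared approximation —
the exact test is the field standard for QC and remains well-defined at
low counts; it is validated against a direct log-factorial enumeration.

# Permutation inference

Empirical P values come from shuffling the phenotype labels of the
analysed contrast, keeping genotypes fixed, and recomputing the allelic
chi-squared for every family variant in each of R permutations (R =
10,000 by default):

* `EMP1 = (1 + #{T_perm >= T_obs}) / (R + 1)` — pointwise;
* `EMP2 = (1 + #{max_family T_perm >= T_obs}) / (R + 1)` — family-wise
  max(T), the multiple-testing-corrected P.

The `+1` estimator avoids zero P values and makes `1/(R+1)` the floor.
The family is all QC-passing variants tested against the given phenotype.
When strata are supplied (e.g. sex), labels are shuffled within strata
only, preserving the covariate-genotype relation. Permutations producing
a zero-margin table score 0 for that variant and are tallied. For toy
cohorts an exhaustive mode enumerates every distinct label assignment, in
which case the estimator drops the `+1` (the observed assignment is part
of the enumeration); this is what the brute-force equivalence tests use.

Calibration is checked empirically: on null cohorts of 39 variants and
300/900 samples with 999 permutations, the family-wise rate of any
`EMP2 <= 0.05` sits within Monte-Carlo error of 0.05 over 500 replicate
datasets, and EMP1 for a fixed common variant is uniform across
replicates (Kolmogorov–Smirnov). One caveat is worth knowing: because
the permuted allelic chi-squared is discrete, the `>=` comparison counts
the tie mass and EMP1 is *conservative* wherever ties are non-negligible
— visibly so for low-MAF variants (mean null EMP1 near 0.57 at MAF 0.1
in our diagnostics, against 0.51–0.52 at MAF 0.4–0.5). That is the
standard validity-over-exactness trade of permutation P values, so the
uniformity check reads EMP1 at a MAF-0.5 variant, where the statistic is
effectively continuous. Those problem sizes keep the full calibration run
in the low minutes on one CPU while leaving the Monte-Carlo standard
error (~0.01) small enough for a meaningful band.

# Weighted genetic risk score

The wGRS multiplies each effect-allele dose by its published log-OR and
divides the sum by the total number of scored alleles:

$$s_i = \frac{\sum_v d_{iv}\,\beta_v}{2\,n_i},$$

where `n_i` counts the sample's non-missing panel variants — missing
variants leave both numerator and denominator, keeping the score a
per-allele average comparable across call rates. Risk categories come
from the 33⅓ and 66⅔ percentiles of the *control* score distribution
(linear-interpolation quantiles, R type 7; the convention is recorded in
output metadata because tertile boundaries are sensitive to it), with a
left-closed assignment rule (`low` iff `score <= t1`). Cases are always
categorised with control-derived cutpoints. Tertile effects are estimated
by logistic regression of the phenotype on medium/high indicators plus
sex, low tertile as reference; analyses with fewer than five events in
the reference tertile are skipped with a reason, generalising the source
analysis's minimum-events footnote. The per-allele-average reading of
"divided by the total number of alleles" follows the cited scoring
method; the alternative (dividing by carried risk alleles) would make the
score a ratio of correlated quantities and was rejected.

Because the 39 published per-SNP ORs are not reprinted in the source, the
packaged weight table (`synthetic_weights()`) is synthetic — plausible
ORs of 1.10–1.40 — and is labelled as such; it exercises the machinery
but does not reproduce the published tertile ORs.

# Clump-and-threshold polygenic score

Summary statistics are clumped greedily: variants inside the
chromosome-6 long-range-LD (MHC) interval, 29.7–33.3 Mb as a closed
interval in the coordinates of the input data (no liftover), are removed
first; remaining variants are visited by ascending P (ties broken by
chromosome, then position, for determinism), each unclaimed visit
becoming an index SNP that claims every unclaimed variant within 250 kb
on the same chromosome with `r^2 > 0.2` against it. LD is the composite
`r^2` — squared Pearson correlation of unphased dose vectors — computed
from the analysis cohort's own genotypes by default. Every run's output
satisfies two assertable post-conditions (checked by brute force in the
tests): retained same-chromosome pairs within the window have
`r^2 <= 0.2`, and every removed variant has a retained neighbour with
smaller P and `r^2 > 0.2`.

Scores at each threshold of the a-priori ladder (0.001, 0.01, 0.05, 0.1,
0.2, 0.3, 0.4, 0.5) are `sum(dose * beta)` over retained variants passing
the threshold. Unlike the wGRS, missing doses are mean-imputed at twice
the cohort effect-allele frequency — no per-sample average is taken here,
so exclusion would make scores incomparable across samples; both choices
are documented in output metadata.

Each threshold's score enters a case-only logistic model with age and sex
(binary sub-phenotypes dictate logistic regression); the reported effect
size is the Nagelkerke pseudo-R² difference between the full and the
covariate-only model (the convention of the standard scoring tool; the
quantity is non-negative up to numerical tolerance because the models are
nested). The best fit is the threshold with smallest P, and its
family-wise empirical P permutes the phenotype labels — covariates stay
attached to their samples — re-selecting the best threshold every time.
The null demonstration in the analysis scripts shows why this matters:
the nominal best-of-eight P is anti-conservative by construction.

# Synthetic cohorts

The generator draws what the analysis assumes:

* independent variants under Hardy–Weinberg equilibrium at stated MAFs
  (X males receive one allele, coded 0/2);
* LD blocks from a shared latent Gaussian factor per haplotype,
  thresholded at the allele frequency, with the factor loading solved
  numerically (base-R `integrate` + `uniroot` on the bivariate normal
  orthant probability) so the haplotype — hence dose — correlation
  matches the square root of the target `r^2`; the solution is exact for
  equal-MAF blocks and approximate otherwise, and targets that exceed
  the binary-correlation bound for the block's MAF range raise an error
  naming the block;
* disease status from an additive logistic model
  `logit P = intercept + sum(beta_v d_v) + beta_sex * female`, with the
  default intercept at a few-percent baseline prevalence so ascertainment
  behaves like a rare-ish disease (the allelic OR then estimates
  `exp(beta)` essentially without bias, which the recovery tests
  quantify: |log-OR bias| < 0.05 for a true OR of 2 at MAF 0.3 with
  600/1800 samples);
* case-control ascertainment by rejection: genotype batches are drawn
  from the population model until the case and control quotas are met;
* case-only sub-phenotype flags from their own logistic models, with an
  `observed` fraction to mirror partial phenotype denominators (e.g.
  mucosal morphology graded for 546 of 625 cases);
* ages uniform on 0.5–79 years, the printed range of the study cohort;
* genotype missingness completely at random.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data — includes population structure and
relatedness, haplotype-phase-level LD (composite LD suffices for
`r^2`-based clumping), genotyping batch effects or differential
missingness mechanisms, and HLA effects. The `study-shape` fixture
reproduces the published cohort's margins (625/1817, the ten printed
control MAFs, the clinical-summary counts such as 489 female and 361/546
TVA/SVA) but its genotypes are null: published per-variant EMP2 values,
tertile ORs and PRS R² cannot be reproduced without the study's
individual-level genotypes, and this package does not pretend to.

All randomness flows from one root seed; fixtures are byte-identical
under the same seed, and every run manifest records the seed and the
convention flags.

# Numerical choices and degenerate inputs

* Exact HWE uses the Wigginton-style recurrence in log space; monomorphic
  variants return P = 1 by convention.
* Zero-margin tables: hard error in the observed statistic (the variant
  is untestable), statistic 0 with a tally inside permutations.
* Breslow–Day expected cell counts solve the OR quadratic and take the
  admissible root; `psi = 1` degenerates to the linear case.
* Strand is never inferred: an effect allele matching neither genotype
  allele is a hard error listing the variants, because curated panels
  should agree exactly. Allele flips map dose `d -> 2 - d`.
* Degenerate control score distributions (coincident tertile cutpoints)
  warn and may leave the medium class empty.
* Quasi-separation in logistic fits is flagged via fitted probabilities
  at the numerical 0/1 boundary.

# Problem sizes used in validation

The packaged validation uses: 500 null datasets x 999 permutations for
the family-wise calibration; 200 replicates each for causal-SNP recovery
(600/1800 samples) and tertile-CI coverage (625/1817 samples); exhaustive
permutation on 6-sample toys; 20-table brute-force comparisons for the
exact HWE and Breslow–Day tests; and a 1000-sample, 52-variant LD panel
for the clumping post-conditions. These sizes were chosen to keep
Monte-Carlo error well inside the asserted bands.
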