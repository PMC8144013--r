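#' The 39-variant coeliac risk panel used by the study-shaped fixture
#'
#' Ten markers carry the control-population minor allele frequencies
#' reported for the Finnish cohort (rs5979785 on X among them); the
#' remaining 29 panel members are synthetic placeholders with fixed,
#' realistic MAFs so the panel totals 39 non-HLA SNPs. Disease log-ORs
#' default to 0 (a null cohort); callers can overwrite `beta`.
#'
#' @return data.frame: `id`, `chrom`, `pos`, `maf`, `beta`.
#' @export
study_variant_panel <- function() {
  named <- data.frame(
    id = c("rs653178", "rs13010713", "rs13151961", "rs11712165",
           "rs10936599", "rs13098911", "rs17810546", "rs2327832",
           "rs2298428", "rs5979785"),
    chrom = c("12", "2", "4", "3", "3", "3", "3", "6", "22", "X"),
    pos = c(111904371, 182308352, 123210229, 119222456, 169492101,
            46210205, 159665050, 138006504, 21979289, 12907658),
    maf = c(0.41, 0.51, 0.12, 0.39, 0.26, 0.14, 0.10, 0.19, 0.29, 0.24),
    stringsAsFactors = FALSE)
  filler_maf <- rep(c(0.45, 0.36, 0.28, 0.22, 0.17, 0.13, 0.33,
                      0.08, 0.48, 0.05), length.out = 29)
  filler <- data.frame(
    id = sprintf("snp%02d", seq_len(29)),
    chrom = as.character(rep(c(1, 2, 5, 7, 8, 9, 10, 11, 13, 14, 15,
                               16, 17, 18, 19, 20, 21), length.out = 29)),
    pos = 10000000 + seq_len(29) * 2500000,
    maf = filler_maf,
    stringsAsFactors = FALSE)
  panel <- rbind(named, filler)
  panel$maf <- pmin(panel$maf, 0.5)
  panel$beta <- 0
  panel
}

#' Synthetic ln(OR) weight table for the 39-variant panel
#'
#' The published per-SNP odds ratios behind the weighted risk score are
#' not reproduced here; these are synthetic but realistic weights
#' (OR 1.10-1.40, deterministic) over the panel's effect alleles, adequate
#' for exercising the scoring and tertile machinery.
#'
#' @return data.frame: `id`, `effect_allele`, `beta`.
#' @export
synthetic_weights <- function() {
  panel <- study_variant_panel()
  ors <- rep(c(1.28, 1.15, 1.36, 1.10, 1.22, 1.31, 1.18, 1.25, 1.12,
               1.40), length.out = nrow(panel))
  data.frame(id = panel$id, effect_allele = "A", beta = log(ors),
             stringsAsFactors = FALSE)
}

# Deterministic flag vector: k ones among n cases, rotated by `shift` so
# the flags are not all nested, then NA outside the observed subset.
flag_vector <- function(n, k, shift, observed = n) {
  v <- integer(n)
  pos <- ((seq_len(k) - 1 + shift) %% observed) + 1
  v[pos] <- 1L
  if (observed < n) v[(observed + 1):n] <- NA
  v
}

#' Study-shaped phenotype table
#'
#' A deterministic 625-case / 1817-control phenotype table whose margins
#' match the published clinical summary: 489 female cases (78%), 44
#' childhood diagnoses, 273 with childhood symptoms, 526 with
#' gastrointestinal symptoms, 267 malabsorption (157 anaemia), 263
#' extraintestinal manifestations (69 dermatitis herpetiformis, 38
#' neurological, 70 fractures), 123 associated conditions (100 AITD, 18
#' T1D), mucosal morphology available for 546 (361 TVA/SVA, 185 PVA),
#' autoantibody status for 298 (19 negative), 527 intermediate/low and 98
#' high HLA risk. Flag co-occurrence is arbitrary (rotated assignment);
#' only the margins are meaningful.
#'
#' @return data.frame in the [join_cohort()] phenotype layout.
#' @export
study_phenotype_table <- function() {
  n_case <- 625; n_ctrl <- 1817
  ids <- sprintf("S%05d", seq_len(n_case + n_ctrl))
  status <- rep(c("case", "control"), c(n_case, n_ctrl))
  sex <- c(rep(c("female", "male"), c(489, n_case - 489)),
           rep(c("female", "male"), length.out = n_ctrl))
  # ages: deterministic grid over the cohort range, median near 41
  age <- c(seq(0.5, 79, length.out = n_case),
           seq(18, 79, length.out = n_ctrl))
  aad <- rep(NA_real_, n_case + n_ctrl)
  # 44 diagnosed at <= 7 years, 573 later, 8 unknown
  aad[1:44] <- seq(0.5, 7, length.out = 44)
  aad[45:617] <- seq(8, 75, length.out = 573)
  ph <- data.frame(sample_id = ids, status = status, sex = sex,
                   age = age, age_at_diagnosis = aad,
                   stringsAsFactors = FALSE)
  f <- function(k, shift, observed = n_case)
    c(flag_vector(n_case, k, shift, observed), rep(NA, n_ctrl))
  ph$childhood_diagnosis <- c(ifelse(is.na(aad[1:n_case]), NA,
                                     as.integer(aad[1:n_case] <= 7)),
                              rep(NA, n_ctrl))
  ph$diagnosed_gt7 <- c(ifelse(is.na(aad[1:n_case]), NA,
                               as.integer(aad[1:n_case] > 7)),
                        rep(NA, n_ctrl))
  ph$childhood_symptoms <- f(273, 40)
  ph$gi_symptoms <- f(526, 0)
  ph$malabsorption <- f(267, 120)
  ph$anaemia <- f(157, 150)
  ph$ei_manifestation <- f(263, 200)
  ph$dh <- f(69, 230)
  ph$neuro <- f(38, 260)
  ph$fractures <- f(70, 300)
  ph$asymptomatic <- f(53, 520)
  ph$assoc_conditions <- f(123, 350)
  ph$aitd <- f(100, 360)
  ph$t1d <- f(18, 400)
  # morphology graded for 546 patients: TVA/SVA 361, PVA the complement
  ph$tva_sva <- f(361, 0, observed = 546)
  ph$pva <- c(ifelse(is.na(ph$tva_sva[1:n_case]), NA,
                     1L - ph$tva_sva[1:n_case]), rep(NA, n_ctrl))
  ph$antibody_negative <- f(19, 100, observed = 298)
  ph$hla_high <- f(98, 450)
  ph
}

#' Write a reproducible on-disk fixture
#'
#' Three named datasets, written in the package's TSV dialect plus a truth
#' manifest and a key-value config echo:
#' \describe{
#'   \item{study-shape}{625 cases / 1817 controls x 39 variants; genotypes
#'     drawn under HWE at the panel's control MAFs (null model), phenotype
#'     margins matching the published clinical summary, plus a synthetic
#'     weight table.}
#'   \item{tiny}{20 samples x 3 variants, for documentation examples.}
#'   \item{ld-demo}{1000 samples x 50 variants in 5 LD blocks (plus two
#'     variants inside the chromosome-6 MHC long-range-LD interval) with a
#'     matching synthetic summary-statistics table, for clumping tests.}
#' }
#'
#' @param name fixture name.
#' @param dir output directory (created if needed).
#' @param seed integer seed; the same seed yields byte-identical files.
#' @return Named character vector of file paths, invisibly; the generated
#'   objects as attribute `"objects"`.
#' @export
make_fixture <- function(name = c("study-shape", "tiny", "ld-demo"),
                         dir = tempfile("fixture"), seed = 20260101) {
  name <- match.arg(name)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genotypes = file.path(dir, paste0(name, ".tsv")),
             phenotypes = file.path(dir, paste0(name, ".pheno.tsv")),
             truth = file.path(dir, paste0(name, ".truth.tsv")),
             config = file.path(dir, paste0(name, ".config.txt")))
  objects <- list()

  if (name == "study-shape") {
    ph <- study_phenotype_table()
    cfg <- sim_config(n_cases = 625, n_controls = 1817,
                      variants = study_variant_panel(),
                      sex_ratio = 0.62, seed = seed)
    set.seed(seed)
    g <- simulate_genotypes(cfg, n = nrow(ph),
                            sex = ph$sex)
    g$dose <- g$dose[seq_len(nrow(ph)), , drop = FALSE]
    rownames(g$dose) <- ph$sample_id
    g$samples <- ph$sample_id
    write_genotypes(g, paths["genotypes"], format = "tsv",
                    status = ph$status)
    utils::write.table(ph, paths["phenotypes"], sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
    w <- synthetic_weights()
    paths["weights"] <- file.path(dir, paste0(name, ".weights.tsv"))
    utils::write.table(w, paths["weights"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    truth <- cfg$variants
    objects <- list(g = g, pheno = ph, weights = w, config = cfg)
  } else if (name == "tiny") {
    cfg <- sim_config(n_cases = 10, n_controls = 10,
                      variants = data.frame(
                        id = c("v1", "v2", "v3"), chrom = "1",
                        pos = c(1000, 2000, 3000),
                        maf = c(0.5, 0.3, 0.2)),
                      seed = seed)
    set.seed(seed)
    g <- simulate_genotypes(cfg, n = 20)
    write_genotypes(g, paths["genotypes"], format = "tsv",
                    status = rep(c("case", "control"), each = 10))
    ph <- data.frame(sample_id = g$samples,
                     status = rep(c("case", "control"), each = 10),
                     sex = g$sex, stringsAsFactors = FALSE)
    utils::write.table(ph, paths["phenotypes"], sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
    truth <- cfg$variants
    objects <- list(g = g, pheno = ph, config = cfg)
  } else { # ld-demo
    blocks <- lapply(seq_len(5), function(b) {
      list(ids = sprintf("b%d_v%02d", b, seq_len(10)),
           r2 = c(0.9, 0.6, 0.4, 0.3, 0.1)[b])
    })
    block_maf <- c(0.3, 0.25, 0.4, 0.2, 0.35)
    variants <- do.call(rbind, lapply(seq_len(5), function(b) {
      data.frame(id = blocks[[b]]$ids,
                 chrom = as.character(b),
                 pos = 50000000 + seq_len(10) * 20000,
                 maf = block_maf[b],
                 stringsAsFactors = FALSE)
    }))
    mhc <- data.frame(id = c("mhc_v1", "mhc_v2"), chrom = "6",
                      pos = c(30000000, 32000000), maf = c(0.3, 0.2),
                      stringsAsFactors = FALSE)
    variants <- rbind(variants, mhc)
    cfg <- sim_config(n_cases = 500, n_controls = 500,
                      variants = variants, ld_blocks = blocks,
                      seed = seed)
    set.seed(seed)
    g <- simulate_genotypes(cfg, n = 1000)
    write_genotypes(g, paths["genotypes"], format = "tsv")
    # synthetic discovery P values: deterministic spread over the ladder
    set.seed(seed + 1)
    ss <- data.frame(id = variants$id, chrom = variants$chrom,
                     pos = variants$pos, effect_allele = "A",
                     beta = round(stats::rnorm(nrow(variants), 0, 0.15), 4),
                     p = round(stats::runif(nrow(variants), 1e-8, 0.6), 8),
                     stringsAsFactors = FALSE)
    paths["sumstats"] <- file.path(dir, paste0(name, ".sumstats.tsv"))
    utils::write.table(ss, paths["sumstats"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    truth <- variants
    objects <- list(g = g, sumstats = ss, config = cfg)
  }

  utils::write.table(truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(c(paste0("fixture\t", name),
               paste0("seed\t", seed),
               paste0("n_variants\t", nrow(truth)),
               "x_male_coding\t0/2",
               "quantile_method\tlinear-interpolation (type 7)"),
             paths["config"])
  attr(paths, "objects") <- objects
  invisible(paths)
}
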