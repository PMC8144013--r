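#' Construct a genotype matrix
#'
#' The central genotype container: a samples x variants matrix of
#' effect-allele dose counts (0, 1, 2 or `NA` for missing), plus a variant
#' table and per-sample sex. The dose counts the variant's `allele_a`
#' (the declared effect allele). On chromosome X, male genotypes are
#' hemizygous and coded on the allele-count scale as 0 or 2; this convention
#' is recorded in the object so downstream analyses can stratify.
#'
#' @param dose integer matrix, samples in rows, variants in columns; values
#'   in 0/1/2 or `NA`. Row names are sample ids, column names variant ids.
#' @param variants data.frame with columns `id`, `chrom` (`"1"`..`"22"`,
#'   `"X"`), `pos` (1-based basepairs), `allele_a` (effect allele),
#'   `allele_b`.
#' @param sex character vector, one of `"male"`, `"female"`, `"unknown"`
#'   per sample.
#' @return An object of class `"genotypes"`.
#' @export
genotype_matrix <- function(dose, variants, sex = NULL) {
  dose <- as.matrix(dose)
  storage.mode(dose) <- "double"
  if (is.null(sex)) sex <- rep("unknown", nrow(dose))
  stopifnot(is.data.frame(variants),
            all(c("id", "chrom", "pos", "allele_a", "allele_b") %in%
                  names(variants)))
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  variants$id <- as.character(variants$id)
  variants$chrom <- as.character(variants$chrom)
  if (anyDuplicated(variants$id))
    stop("duplicate variant id(s): ",
         paste(unique(variants$id[duplicated(variants$id)]), collapse = ", "))
  if (any(variants$allele_a == variants$allele_b))
    stop("allele_a must differ from allele_b")
  if (any(variants$pos < 1)) stop("positions must be >= 1 (1-based)")
  if (ncol(dose) != nrow(variants))
    stop("dose has ", ncol(dose), " columns but ", nrow(variants),
         " variants declared")
  if (length(sex) != nrow(dose))
    stop("sex has length ", length(sex), ", expected ", nrow(dose))
  if (!all(sex %in% c("male", "female", "unknown")))
    stop("sex must be 'male', 'female' or 'unknown'")
  bad <- !(dose %in% c(0, 1, 2) | is.na(dose))
  if (any(bad)) stop("dose values must be 0, 1, 2 or NA")
  on_x <- variants$chrom == "X"
  if (any(on_x) && any(sex == "male")) {
    male_x <- dose[sex == "male", on_x, drop = FALSE]
    if (any(male_x == 1, na.rm = TRUE))
      stop("male X-chromosome doses must be 0 or 2 (hemizygote convention)")
  }
  if (is.null(rownames(dose)))
    rownames(dose) <- paste0("S", seq_len(nrow(dose)))
  colnames(dose) <- variants$id
  structure(
    list(dose = dose, variants = variants, sex = sex,
         samples = rownames(dose)),
    class = "genotypes",
    x_male_coding = "0/2"
  )
}

#' @export
print.genotypes <- function(x, ...) {
  cat("genotypes: ", length(x$samples), " samples x ",
      nrow(x$variants), " variants\n", sep = "")
  n_x <- sum(x$variants$chrom == "X")
  if (n_x) cat("  ", n_x, " X-chromosome variant(s), male coding ",
               attr(x, "x_male_coding"), "\n", sep = "")
  miss <- mean(is.na(x$dose))
  cat(sprintf("  missingness %.2f%%; sex: %d male / %d female / %d unknown\n",
              100 * miss, sum(x$sex == "male"), sum(x$sex == "female"),
              sum(x$sex == "unknown")))
  invisible(x)
}

sex_from_plink <- function(code, line_no) {
  out <- c(`1` = "male", `2` = "female", `0` = "unknown")[as.character(code)]
  if (any(is.na(out)))
    stop("invalid sex code '", code[which(is.na(out))[1]],
         "' at .ped line ", line_no[which(is.na(out))[1]],
         " (expected 0, 1 or 2)")
  unname(out)
}

sex_to_plink <- function(sex) {
  unname(c(male = "1", female = "2", unknown = "0")[sex])
}

read_plink_text <- function(path, a1 = NULL) {
  prefix <- sub("\\.(ped|map)$", "", path)
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  for (p in c(ped_path, map_path))
    if (!file.exists(p)) stop("file not found: ", p)

  map_lines <- readLines(map_path)
  map_fields <- strsplit(trimws(map_lines), "[ \t]+")
  nf <- lengths(map_fields)
  if (any(nf != 4))
    stop("malformed .map row at line ", which(nf != 4)[1],
         ": expected 4 fields, got ", nf[nf != 4][1])
  map <- do.call(rbind, map_fields)
  variants <- data.frame(id = map[, 2], chrom = map[, 1],
                         pos = as.integer(map[, 4]),
                         stringsAsFactors = FALSE)
  if (anyDuplicated(variants$id))
    stop("duplicate variant id in .map: ",
         variants$id[duplicated(variants$id)][1])
  m <- nrow(variants)

  ped_lines <- readLines(ped_path)
  ped_fields <- strsplit(trimws(ped_lines), "[ \t]+")
  nf <- lengths(ped_fields)
  expected <- 6 + 2 * m
  if (any(nf != expected))
    stop("malformed .ped row at line ", which(nf != expected)[1],
         ": expected ", expected, " fields, got ", nf[nf != expected][1])
  ped <- do.call(rbind, ped_fields)
  samples <- ped[, 2]
  sex <- sex_from_plink(ped[, 5], seq_len(nrow(ped)))

  al1 <- ped[, 6 + 2 * seq_len(m) - 1, drop = FALSE]
  al2 <- ped[, 6 + 2 * seq_len(m), drop = FALSE]
  al1[al1 == "0"] <- NA
  al2[al2 == "0"] <- NA
  # half-missing genotypes are treated as fully missing
  half <- xor(is.na(al1), is.na(al2))
  al1[half] <- NA
  al2[half] <- NA

  dose <- matrix(NA_real_, nrow(ped), m,
                 dimnames = list(samples, variants$id))
  allele_a <- allele_b <- character(m)
  for (j in seq_len(m)) {
    obs <- c(al1[, j], al2[, j])
    alleles <- sort(unique(obs[!is.na(obs)]))
    if (length(alleles) > 2)
      stop("variant ", variants$id[j], " has >2 alleles: ",
           paste(alleles, collapse = "/"))
    eff <- if (!is.null(a1) && variants$id[j] %in% names(a1)) {
      a1[[variants$id[j]]]
    } else if (length(alleles) <= 1) {
      if (length(alleles)) alleles[1] else "A"
    } else {
      # PLINK convention: A1 is the minor allele (lexicographic tie-break)
      cnt <- table(factor(obs, levels = alleles))
      alleles[order(cnt, alleles)][1]
    }
    other <- setdiff(alleles, eff)
    if (length(other) > 1)
      stop("variant ", variants$id[j], ": declared A1 '", eff,
           "' not among observed alleles ", paste(alleles, collapse = "/"))
    allele_a[j] <- eff
    allele_b[j] <- if (length(other)) other[1] else "*"
    dose[, j] <- (al1[, j] == eff) + (al2[, j] == eff)
  }
  variants$allele_a <- allele_a
  variants$allele_b <- allele_b
  genotype_matrix(dose, variants, sex)
}

read_tsv_dosage <- function(path, variants_file = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, na.strings = c("NA", ""))
  if (!"sample_id" %in% names(tab))
    stop("TSV dosage table must have a 'sample_id' column")
  reserved <- intersect(c("sample_id", "sex", "status"), names(tab))
  vids <- setdiff(names(tab), reserved)
  if (!length(vids)) stop("no variant columns found in ", path)
  if (anyDuplicated(vids))
    stop("duplicate variant id: ", vids[duplicated(vids)][1])
  dose <- as.matrix(tab[, vids, drop = FALSE])
  bad <- which(!(dose %in% c(0, 1, 2) | is.na(dose)), arr.ind = TRUE)
  if (nrow(bad))
    stop("malformed dose at data row ", bad[1, 1], ", variant ",
         vids[bad[1, 2]], ": '", dose[bad[1, , drop = FALSE]], "'")
  rownames(dose) <- tab$sample_id
  sex <- if ("sex" %in% names(tab)) {
    if (!all(tab$sex %in% c("male", "female", "unknown")))
      stop("sex column must be male/female/unknown")
    tab$sex
  } else rep("unknown", nrow(tab))
  if (!is.null(variants_file)) {
    variants <- utils::read.delim(variants_file, stringsAsFactors = FALSE)
    need <- c("id", "chrom", "pos", "allele_a", "allele_b")
    if (!all(need %in% names(variants)))
      stop("variants file must have columns ", paste(need, collapse = ", "))
    variants <- variants[match(vids, variants$id), ]
    if (anyNA(variants$id))
      stop("variants file missing metadata for: ",
           paste(vids[is.na(variants$id)], collapse = ", "))
  } else {
    variants <- data.frame(id = vids, chrom = "1",
                           pos = seq_along(vids),
                           allele_a = "A", allele_b = "B",
                           stringsAsFactors = FALSE)
  }
  g <- genotype_matrix(dose, variants, sex)
  if ("status" %in% names(tab)) attr(g, "status") <- tab$status
  g
}

read_vcf_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  if (anyDuplicated(ids)) stop("duplicate variant id in VCF")
  # dose counts the ALT allele (declared effect allele)
  gtv <- gsub("\\|", "/", as.vector(gt))
  miss <- is.na(gtv) | grepl("\\.", gtv)
  cnt <- vapply(strsplit(gtv, "/"), function(a) sum(a == "1"), numeric(1))
  cnt[miss] <- NA_real_
  dose <- matrix(cnt, nrow = nrow(gt), ncol = ncol(gt),
                 dimnames = list(ids, colnames(gt)))
  variants <- data.frame(id = ids, chrom = as.character(fix[, "CHROM"]),
                         pos = as.integer(fix[, "POS"]),
                         allele_a = fix[, "ALT"], allele_b = fix[, "REF"],
                         stringsAsFactors = FALSE)
  genotype_matrix(t(dose), variants, rep("unknown", ncol(dose)))
}

#' Read genotypes from PLINK text, TSV dosage or VCF
#'
#' @param path for `"plink-text"`, the file-set prefix or the `.ped` path
#'   (the `.map` must sit alongside); for the other dialects, the file path.
#' @param format one of `"plink-text"`, `"tsv"`, `"vcf"`.
#' @param a1 optional named character vector (variant id -> effect allele)
#'   declaring A1 for PLINK text input; defaults to the minor allele.
#' @param variants_file optional TSV with variant metadata
#'   (`id`, `chrom`, `pos`, `allele_a`, `allele_b`) for the TSV dialect.
#' @return A [genotype_matrix()] object. Missing genotypes (`0` in PLINK
#'   text, `.` in VCF, empty cell in TSV) become `NA`.
#' @export
read_genotypes <- function(path, format = c("plink-text", "tsv", "vcf"),
                           a1 = NULL, variants_file = NULL) {
  format <- match.arg(format)
  switch(format,
         "plink-text" = read_plink_text(path, a1 = a1),
         "tsv" = read_tsv_dosage(path, variants_file = variants_file),
         "vcf" = read_vcf_genotypes(path))
}

#' Write genotypes to PLINK text or TSV dosage
#'
#' @param g a [genotype_matrix()] object.
#' @param path output prefix (plink-text, writes `.ped` + `.map`) or file
#'   path (tsv; variant metadata goes to `<path>.variants.tsv`).
#' @param format `"plink-text"` or `"tsv"` (VCF is read-only here).
#' @param status optional per-sample status column for the TSV dialect.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("plink-text", "tsv"),
                            status = NULL) {
  format <- match.arg(format)
  if (format == "plink-text") {
    prefix <- sub("\\.(ped|map)$", "", path)
    v <- g$variants
    utils::write.table(
      data.frame(v$chrom, v$id, 0, v$pos),
      paste0(prefix, ".map"),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    m <- nrow(v)
    geno <- matrix("0", length(g$samples), 2 * m)
    for (j in seq_len(m)) {
      d <- g$dose[, j]
      a <- v$allele_a[j]; b <- v$allele_b[j]
      first <- ifelse(is.na(d), "0", ifelse(d >= 1, a, b))
      second <- ifelse(is.na(d), "0", ifelse(d == 2, a, b))
      geno[, 2 * j - 1] <- first
      geno[, 2 * j] <- second
    }
    ped <- cbind(g$samples, g$samples, "0", "0", sex_to_plink(g$sex),
                 "-9", geno)
    utils::write.table(ped, paste0(prefix, ".ped"), sep = " ",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    tab <- data.frame(sample_id = g$samples, sex = g$sex,
                      stringsAsFactors = FALSE, check.names = FALSE)
    if (!is.null(status)) tab$status <- status
    tab <- cbind(tab, as.data.frame(g$dose, check.names = FALSE))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    utils::write.table(g$variants, paste0(path, ".variants.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Orient dosages to a weight table's effect alleles
#'
#' Scores interpret beta as the effect of one copy of a named allele, so the
#' dose must count that allele. Variants whose stored effect allele is the
#' weight table's other allele are flipped (`d -> 2 - d`, alleles swapped);
#' an allele matching neither is a hard error — no strand inference is
#' attempted because curated panels should agree exactly.
#'
#' @param g a [genotype_matrix()].
#' @param w a weight table (data.frame with `id`, `effect_allele`; see
#'   [read_weight_table()]). Every `w` variant must be present in `g`.
#' @return `g` with doses counting `w$effect_allele`.
#' @export
align_to_effect_allele <- function(g, w) {
  idx <- match(w$id, g$variants$id)
  if (anyNA(idx))
    stop("weight-table variants absent from genotypes: ",
         paste(w$id[is.na(idx)], collapse = ", "))
  va <- g$variants$allele_a[idx]
  vb <- g$variants$allele_b[idx]
  keep <- w$effect_allele == va
  flip <- w$effect_allele == vb
  bad <- !(keep | flip)
  if (any(bad))
    stop("effect allele matches neither genotype allele for: ",
         paste(sprintf("%s (weights %s, genotypes %s/%s)",
                       w$id[bad], w$effect_allele[bad], va[bad], vb[bad]),
               collapse = "; "))
  fj <- idx[flip]
  if (length(fj)) {
    g$dose[, fj] <- 2 - g$dose[, fj]
    tmp <- g$variants$allele_a[fj]
    g$variants$allele_a[fj] <- g$variants$allele_b[fj]
    g$variants$allele_b[fj] <- tmp
  }
  g
}

#' Join genotypes with a phenotype table on sample id
#'
#' Inner join; samples present on only one side are dropped and counted.
#'
#' @param g a [genotype_matrix()].
#' @param pheno data.frame with a `sample_id` column plus `status`
#'   (`"case"`/`"control"`), covariates and binary phenotype flags.
#' @return A list of class `"cohort"` with elements `g`, `pheno` (aligned,
#'   same sample order) and `dropped` (named counts).
#' @export
join_cohort <- function(g, pheno) {
  stopifnot("sample_id" %in% names(pheno))
  common <- intersect(g$samples, pheno$sample_id)
  if (!length(common))
    stop("no samples shared between genotypes and phenotypes")
  dropped <- c(genotype_only = length(setdiff(g$samples, common)),
               phenotype_only = length(setdiff(pheno$sample_id, common)))
  gi <- match(common, g$samples)
  g$dose <- g$dose[gi, , drop = FALSE]
  g$sex <- g$sex[gi]
  g$samples <- common
  pheno <- pheno[match(common, pheno$sample_id), , drop = FALSE]
  rownames(pheno) <- NULL
  if (any(dropped))
    message(dropped["genotype_only"], " genotype-only and ",
            dropped["phenotype_only"], " phenotype-only sample(s) dropped")
  structure(list(g = g, pheno = pheno, dropped = dropped),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("cohort: ", length(x$g$samples), " samples (",
      sum(x$pheno$status == "case"), " cases / ",
      sum(x$pheno$status == "control"), " controls), ",
      nrow(x$g$variants), " variants\n", sep = "")
  invisible(x)
}

#' Read a SNP weight table (variant, effect allele, beta = ln OR)
#'
#' @param path TSV with header; mandatory columns `id`, `effect_allele`,
#'   `beta` (natural-log odds ratio).
#' @return data.frame with those columns.
#' @export
read_weight_table <- function(path) {
  w <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "effect_allele", "beta")
  if (!all(need %in% names(w)))
    stop("weight table must have columns ", paste(need, collapse = ", "))
  if (any(!is.finite(w$beta))) stop("weight-table beta must be finite")
  if (anyDuplicated(w$id)) stop("duplicate variant id in weight table")
  w
}

#' Read GWAS summary statistics (variant, position, effect allele, beta, p)
#'
#' @param path TSV with header; mandatory columns `id`, `chrom`, `pos`,
#'   `effect_allele`, `beta`, `p` (beta on the natural-log odds scale).
#' @return data.frame, one row per variant.
#' @export
read_sumstats <- function(path) {
  s <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "chrom", "pos", "effect_allele", "beta", "p")
  if (!all(need %in% names(s)))
    stop("summary statistics must have columns ",
         paste(need, collapse = ", "))
  s$chrom <- as.character(s$chrom)
  if (any(s$p <= 0 | s$p > 1)) stop("summary-statistic p must be in (0, 1]")
  if (any(!is.finite(s$beta))) stop("summary-statistic beta must be finite")
  if (anyDuplicated(s$id)) stop("duplicate variant id in summary statistics")
  s
}
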