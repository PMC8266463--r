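# Plain-text serialization of cohorts and genotypes. The cohort and growth
# tables are TSV; genotypes go out either as VCF 4.2 with a per-sample DS
# (effect-allele dosage) field, or as a wide dosage TSV with a companion
# variant table. Both genotype routes round-trip to identical matrices.

#' Write a cohort table as TSV
#'
#' Columns: family_id, child_id, mother_id, father_id, sex,
#' adult_height_cm, mother_height_cm, father_height_cm,
#' true_genetic_value_cm (optional). Missing parental heights are written
#' as empty fields and read back as NA.
#'
#' @param cohort Cohort data.frame (as in a `trio_cohort`).
#' @param path Output file path.
#' @export
write_cohort_tsv <- function(cohort, path) {
  .write_tsv(cohort, path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  co <- .read_tsv(path)
  .assert(all(c("child_id", "sex", "adult_height_cm") %in% names(co)),
          "cohort table must have child_id, sex and adult_height_cm columns")
  co$sex <- .norm_sex(co$sex)
  co
}

#' Write growth records as TSV
#' @param growth data.frame with child_id, age_years, height_cm, weight_kg.
#' @param path Output file path.
#' @export
write_growth_tsv <- function(growth, path) .write_tsv(growth, path)

#' @rdname write_growth_tsv
#' @export
read_growth_tsv <- function(path) .read_tsv(path)

#' Write genotypes as VCF 4.2 with dosage field
#'
#' REF is the other allele, ALT the effect allele; the per-sample `DS`
#' field carries the effect-allele dosage and `GT` a consistent unphased
#' genotype. The effect-allele frequency is stored as `AF` in INFO so the
#' file round-trips through [read_genotypes_vcf()] losslessly.
#'
#' @param genotypes A [genotype_matrix()].
#' @param path Output `.vcf` path (uncompressed).
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  v <- genotypes$variants
  d <- genotypes$dosages
  gt_code <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(v)), function(j) {
    ds <- d[, j]
    gt <- ifelse(is.na(ds), "./.", gt_code[ds + 1L])
    cell <- paste0(gt, ":", ifelse(is.na(ds), ".", format(ds)))
    paste(c(v$chr[j], v$pos[j], v$id[j], v$other_allele[j],
            v$effect_allele[j], ".", "PASS",
            sprintf("AF=%.6g", v$freq[j]), "GT:DS", cell),
          collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=statureprs",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Effect (ALT) allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Effect allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(d)), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_genotypes_vcf
#' @export
read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  af <- suppressWarnings(as.numeric(sub("^.*AF=([0-9.eE+-]+).*$", "\\1",
                                        fix$INFO)))
  variants <- data.frame(
    id = fix$ID, chr = fix$CHROM, pos = as.integer(fix$POS),
    effect_allele = fix$ALT, other_allele = fix$REF, freq = af,
    stringsAsFactors = FALSE
  )
  d <- t(ds)
  colnames(d) <- variants$id
  genotype_matrix(d, variants)
}

#' Write genotypes as a wide dosage TSV
#'
#' First column `sample_id`, one column per variant (effect-allele dosage).
#' A companion variant table (id, chr, pos, effect_allele, other_allele,
#' freq) is written alongside so allele labels survive the round trip.
#'
#' @param genotypes A [genotype_matrix()].
#' @param path Output TSV path.
#' @param variants_path Companion variant-table path; defaults to
#'   `<path>.variants.tsv`.
#' @export
write_dosage_tsv <- function(genotypes, path,
                             variants_path = paste0(path, ".variants.tsv")) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  df <- data.frame(sample_id = rownames(genotypes$dosages),
                   genotypes$dosages, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
  .write_tsv(genotypes$variants, variants_path)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path,
                            variants_path = paste0(path, ".variants.tsv")) {
  df <- .read_tsv(path)
  variants <- .read_tsv(variants_path)
  variants$chr <- as.character(variants$chr)
  d <- as.matrix(df[, -1, drop = FALSE])
  rownames(d) <- df$sample_id
  storage.mode(d) <- "double"
  genotype_matrix(d, variants)
}

#' Write all artifacts of a trio cohort to a directory
#'
#' Writes `cohort.tsv`, `growth.tsv` (when present) and genotypes as
#' `genotypes.vcf` (default) or `dosages.tsv`. Ids are cross-checked
#' between tables before writing.
#'
#' @param sim A `trio_cohort`.
#' @param dir Output directory (created if needed).
#' @param genotype_format `"vcf"` or `"tsv"`.
#' @return Named character vector of written paths.
#' @export
write_cohort <- function(sim, dir, genotype_format = c("vcf", "tsv")) {
  stopifnot(inherits(sim, "trio_cohort"))
  genotype_format <- match.arg(genotype_format)
  ids_geno <- rownames(sim$genotypes$dosages)
  .assert(all(sim$cohort$child_id %in% ids_geno),
          "id mismatch: every child in the cohort table needs genotype rows")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(cohort = file.path(dir, "cohort.tsv"))
  write_cohort_tsv(sim$cohort, paths[["cohort"]])
  if (!is.null(sim$growth)) {
    .assert(all(sim$growth$child_id %in% sim$cohort$child_id),
            "id mismatch: growth records for unknown children")
    paths[["growth"]] <- file.path(dir, "growth.tsv")
    write_growth_tsv(sim$growth, paths[["growth"]])
  }
  if (genotype_format == "vcf") {
    paths[["genotypes"]] <- file.path(dir, "genotypes.vcf")
    write_genotypes_vcf(sim$genotypes, paths[["genotypes"]])
  } else {
    paths[["genotypes"]] <- file.path(dir, "dosages.tsv")
    write_dosage_tsv(sim$genotypes, paths[["genotypes"]])
  }
  paths
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  cohort <- read_cohort_tsv(file.path(dir, "cohort.tsv"))
  growth <- NULL
  gpath <- file.path(dir, "growth.tsv")
  if (file.exists(gpath)) growth <- read_growth_tsv(gpath)
  vcf <- file.path(dir, "genotypes.vcf")
  genotypes <- if (file.exists(vcf)) read_genotypes_vcf(vcf) else
    read_dosage_tsv(file.path(dir, "dosages.tsv"))
  structure(list(cohort = cohort, genotypes = genotypes, effects = NULL,
                 growth = growth, params = NULL),
            class = "trio_cohort")
}
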