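# PGS-Catalog-style scoring files, allele harmonization against a genotype
# panel, raw and standardized polygenic scores, and calibration of the
# standardized score to centimeter-scale predicted heights.

#' Construct a polygenic score model
#'
#' @param variants data.frame with columns `id`, `chr`, `pos`,
#'   `effect_allele`, `other_allele`, `effect_weight` (cm per effect
#'   allele). `chr`/`pos` may be NA when records are rsID-keyed.
#' @param name Score name (metadata).
#' @param genome_build Genome build label (metadata).
#' @return Object of class `prs_model`.
#' @export
prs_model <- function(variants, name = "unnamed_score",
                      genome_build = "simulated") {
  need <- c("id", "effect_allele", "other_allele", "effect_weight")
  .assert(all(need %in% names(variants)),
          paste("scoring model needs columns:", paste(need, collapse = ", ")))
  if (!"chr" %in% names(variants)) variants$chr <- NA_character_
  if (!"pos" %in% names(variants)) variants$pos <- NA_integer_
  dup <- variants$id[duplicated(variants$id)]
  .assert(length(dup) == 0,
          paste("duplicate variant ids:", paste(unique(dup), collapse = ", ")))
  .assert(all(is.finite(variants$effect_weight)),
          "effect weights must be finite")
  variants <- variants[c("id", "chr", "pos", "effect_allele",
                         "other_allele", "effect_weight")]
  rownames(variants) <- NULL
  structure(list(variants = variants,
                 metadata = list(name = name, genome_build = genome_build,
                                 variants_number = nrow(variants))),
            class = "prs_model")
}

#' @export
print.prs_model <- function(x, ...) {
  cat(sprintf("prs_model '%s': %d variants (build %s)\n",
              x$metadata$name, nrow(x$variants), x$metadata$genome_build))
  print(utils::head(x$variants, 5), row.names = FALSE)
  if (nrow(x$variants) > 5) cat("  ...\n")
  invisible(x)
}

#' @export
length.prs_model <- function(x) nrow(x$variants)

#' Read a PGS-Catalog-style scoring file
#'
#' Expects '#'-prefixed metadata lines, then a tab-separated header row and
#' records. Both the rsID-keyed and the (chr_name, chr_position)-keyed
#' dialects are accepted; `effect_allele` and `effect_weight` are required.
#'
#' @param path Scoring file path.
#' @return A [prs_model()].
#' @export
read_scoring_file <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#+\\s*", "", ml)
    if (grepl("=", kv, fixed = TRUE)) {
      k <- sub("=.*$", "", kv)
      meta[[trimws(k)]] <- trimws(sub("^[^=]*=", "", kv))
    }
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  .assert(length(body) >= 1, "scoring file has no header row")
  tab <- utils::read.delim(text = paste(body, collapse = "\n"),
                           sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character")
  for (col in c("effect_allele", "effect_weight")) {
    .assert(col %in% names(tab),
            paste0("scoring file missing required column '", col, "'"))
  }
  has_rsid <- "rsID" %in% names(tab)
  has_pos <- all(c("chr_name", "chr_position") %in% names(tab))
  .assert(has_rsid || has_pos,
          "scoring file must carry rsID or chr_name/chr_position keys")
  w <- suppressWarnings(as.numeric(tab$effect_weight))
  bad <- which(is.na(w) & nzchar(tab$effect_weight))
  .assert(length(bad) == 0,
          paste0("non-numeric effect_weight at data row ",
                 paste(bad, collapse = ", ")))
  .assert(!anyNA(w), "missing effect_weight values")
  id <- if (has_rsid) tab$rsID else
    paste0(tab$chr_name, ":", tab$chr_position)
  variants <- data.frame(
    id = id,
    chr = if (has_pos) tab$chr_name else NA_character_,
    pos = if (has_pos) suppressWarnings(as.integer(tab$chr_position)) else
      NA_integer_,
    effect_allele = toupper(tab$effect_allele),
    other_allele = if ("other_allele" %in% names(tab))
      toupper(tab$other_allele) else NA_character_,
    effect_weight = w,
    stringsAsFactors = FALSE
  )
  model <- prs_model(variants,
                     name = meta$pgs_name %||% basename(path),
                     genome_build = meta$genome_build %||% "unknown")
  if (!is.null(meta$variants_number)) {
    .assert(as.integer(meta$variants_number) == nrow(variants),
            "declared variants_number does not match record count")
  }
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_scoring_file
#' @param model A [prs_model()].
#' @export
write_scoring_file <- function(model, path) {
  stopifnot(inherits(model, "prs_model"))
  v <- model$variants
  keyed_pos <- !anyNA(v$chr) && !anyNA(v$pos)
  header <- c(
    "### PGS-Catalog-style scoring file",
    paste0("#pgs_name=", model$metadata$name),
    paste0("#genome_build=", model$metadata$genome_build),
    paste0("#variants_number=", nrow(v))
  )
  tab <- data.frame(rsID = v$id, stringsAsFactors = FALSE)
  if (keyed_pos) {
    tab$chr_name <- v$chr
    tab$chr_position <- v$pos
  }
  tab$effect_allele <- v$effect_allele
  tab$other_allele <- v$other_allele
  tab$effect_weight <- format(v$effect_weight, digits = 12, trim = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Harmonize a score model against a genotype panel
#'
#' Variants are matched by id. Exact allele matches are kept; variants
#' whose effect/other alleles are swapped relative to the panel are kept
#' and flagged for dosage complementation (d -> 2 - d) at scoring time;
#' variants absent from the panel, or with allele pairs inconsistent with
#' both orientations, are discarded and counted. Strand-ambiguous (A/T,
#' C/G) variants are kept by default when ids match; set
#' `drop_palindromic = TRUE` for real-data use.
#'
#' @param model A [prs_model()].
#' @param genotypes A [genotype_matrix()] whose variants carry allele
#'   labels.
#' @param drop_palindromic Discard A/T and C/G variants.
#' @return Object of class `prs_harmonization`: `model` (harmonized, with a
#'   logical `flip` column), and `report` with kept/flipped/discarded
#'   counts and discarded ids. kept + flipped + discarded always equals the
#'   input model size.
#' @export
harmonize_variants <- function(model, genotypes, drop_palindromic = FALSE) {
  stopifnot(inherits(model, "prs_model"),
            inherits(genotypes, "genotype_matrix"))
  v <- model$variants
  pv <- genotypes$variants
  m <- match(v$id, pv$id)
  palindromic <- (v$effect_allele == "A" & v$other_allele == "T") |
    (v$effect_allele == "T" & v$other_allele == "A") |
    (v$effect_allele == "C" & v$other_allele == "G") |
    (v$effect_allele == "G" & v$other_allele == "C")
  present <- !is.na(m)
  same <- present & v$effect_allele == pv$effect_allele[m] &
    (is.na(v$other_allele) | v$other_allele == pv$other_allele[m])
  flip <- present & !same & v$effect_allele == pv$other_allele[m] &
    (is.na(v$other_allele) | v$other_allele == pv$effect_allele[m])
  keep <- (same | flip) & !(drop_palindromic & palindromic %in% TRUE)
  harmonized <- v[keep, , drop = FALSE]
  harmonized$flip <- flip[keep]
  rownames(harmonized) <- NULL
  report <- list(
    kept = sum(same & keep),
    flipped = sum(flip & keep),
    discarded = sum(!keep),
    discarded_ids = v$id[!keep],
    total = nrow(v)
  )
  out <- model
  out$variants <- harmonized
  out$metadata$variants_number <- nrow(harmonized)
  structure(list(model = out, report = report),
            class = "prs_harmonization")
}

#' @export
print.prs_harmonization <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "harmonization: %d kept, %d flipped, %d discarded (of %d)\n",
    r$kept, r$flipped, r$discarded, r$total))
  invisible(x)
}

#' Compute polygenic scores
#'
#' Raw score per sample = sum over harmonized variants of
#' weight x effect-allele dosage, with flagged variants scored on the
#' complemented dosage (2 - d). Sporadically missing dosages are imputed to
#' 2 x (panel effect-allele frequency) under the default policy, or to the
#' per-variant mean observed effect-allele dosage under `"mean"`.
#'
#' @param harmonized A `prs_harmonization` (or an already-harmonized
#'   [prs_model()] with a `flip` column).
#' @param genotypes A [genotype_matrix()].
#' @param missing_policy `"freq"` or `"mean"`.
#' @return Object of class `score_vector`: data.frame with `sample_id`,
#'   `raw_score`, `std_score` (NA until [standardize_scores()]) and
#'   `n_variants_used` (variants with observed dosage).
#' @export
compute_scores <- function(harmonized, genotypes,
                           missing_policy = c("freq", "mean")) {
  missing_policy <- match.arg(missing_policy)
  model <- if (inherits(harmonized, "prs_harmonization"))
    harmonized$model else harmonized
  stopifnot(inherits(model, "prs_model"),
            inherits(genotypes, "genotype_matrix"))
  v <- model$variants
  .assert(nrow(v) > 0, "zero harmonized variants: no score possible")
  .assert("flip" %in% names(v),
          "model must be harmonized before scoring (no flip column)")
  ci <- match(v$id, colnames(genotypes$dosages))
  .assert(!anyNA(ci), "harmonized model contains variants absent from panel")
  d <- genotypes$dosages[, ci, drop = FALSE]
  # orient every column to the model's effect allele
  if (any(v$flip)) {
    d[, v$flip] <- 2 - d[, v$flip, drop = FALSE]
  }
  used <- rowSums(!is.na(d))
  if (anyNA(d)) {
    fill <- switch(missing_policy,
      freq = {
        f <- genotypes$variants$freq[ci]
        f <- ifelse(v$flip, 1 - f, f)
        if (anyNA(f)) {
          est <- colMeans(d, na.rm = TRUE) / 2
          f[is.na(f)] <- est[is.na(f)]
        }
        2 * f
      },
      mean = colMeans(d, na.rm = TRUE))
    idx <- which(is.na(d))
    d[idx] <- fill[((idx - 1) %/% nrow(d)) + 1]
  }
  raw <- as.numeric(d %*% v$effect_weight)
  out <- data.frame(sample_id = rownames(genotypes$dosages),
                    raw_score = raw, std_score = NA_real_,
                    n_variants_used = as.integer(used),
                    stringsAsFactors = FALSE)
  class(out) <- c("score_vector", "data.frame")
  out
}

#' Standardize polygenic scores within a reference group
#'
#' standardized = (raw - reference mean) / reference SD.
#'
#' @param scores A `score_vector` from [compute_scores()].
#' @param reference Sample ids or a logical vector defining the reference
#'   group; NULL uses all samples.
#' @return The `score_vector` with `std_score` filled in.
#' @export
standardize_scores <- function(scores, reference = NULL) {
  .assert(is.data.frame(scores) && "raw_score" %in% names(scores),
          "scores must come from compute_scores()")
  sel <- if (is.null(reference)) rep(TRUE, nrow(scores)) else
    if (is.logical(reference)) reference else
      scores$sample_id %in% reference
  .assert(sum(sel) >= 2, "reference group needs at least 2 samples")
  mu <- mean(scores$raw_score[sel])
  sd_ref <- stats::sd(scores$raw_score[sel])
  .assert(sd_ref > 0, "zero reference-group SD: cannot standardize")
  scores$std_score <- (scores$raw_score - mu) / sd_ref
  attr(scores, "reference") <- list(mean = mu, sd = sd_ref)
  scores
}

#' Calibrate standardized scores to centimeter-scale predicted heights
#'
#' Least-squares fit of adult height on the standardized score with
#' sex-specific intercepts, on a training split disjoint from any
#' evaluation. Predicted height = sex intercept + slope x standardized
#' score.
#'
#' @param scores A standardized `score_vector`.
#' @param heights Adult heights (cm), aligned with `scores`.
#' @param sex Sex per sample.
#' @param training Sample ids or logical vector marking the training split.
#' @return Object of class `prs_calibration` with a [predict()] method.
#' @export
calibrate_to_cm <- function(scores, heights, sex, training = NULL) {
  .assert(!anyNA(scores$std_score), "standardize scores before calibration")
  sex <- .norm_sex(sex)
  sel <- if (is.null(training)) rep(TRUE, nrow(scores)) else
    if (is.logical(training)) training else scores$sample_id %in% training
  .assert(sum(sel) > 3, "calibration training split too small")
  fit <- stats::lm(heights[sel] ~ 0 + sex[sel] + scores$std_score[sel])
  cf <- stats::coef(fit)
  structure(list(
    intercepts = c(female = unname(cf[1]), male = unname(cf[2])),
    slope = unname(cf[3]),
    training_ids = scores$sample_id[sel]
  ), class = "prs_calibration")
}

#' @export
print.prs_calibration <- function(x, ...) {
  cat(sprintf(
    "prs_calibration: %.2f cm per SD; intercepts %.1f (F) / %.1f (M) cm; fitted on %d samples\n",
    x$slope, x$intercepts[["female"]], x$intercepts[["male"]],
    length(x$training_ids)))
  invisible(x)
}

#' @export
#' @param object A `prs_calibration`.
#' @param std_score Standardized scores to convert.
#' @param sex Sex per sample.
#' @param ... Unused.
#' @rdname calibrate_to_cm
predict.prs_calibration <- function(object, std_score, sex, ...) {
  sex <- .norm_sex(sex)
  unname(object$intercepts[as.character(sex)] + object$slope * std_score)
}

#' @rdname compute_scores
#' @param path Output TSV path.
#' @export
write_scores_tsv <- function(scores, path) {
  .write_tsv(as.data.frame(scores), path)
}

#' @rdname compute_scores
#' @export
read_scores_tsv <- function(path) {
  out <- .read_tsv(path)
  class(out) <- c("score_vector", "data.frame")
  out
}
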