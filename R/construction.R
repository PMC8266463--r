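# Desk-scale polygenic score construction: marginal association scan,
# fixed-effect inverse-variance meta-analysis, greedy LD clumping with
# p-value thresholding, a LASSO arm fitted by cyclic coordinate descent,
# and candidate selection on a held-out model-selection split.

#' Marginal association scan of height on dosage
#'
#' Per-variant least-squares effect of effect-allele dosage on the
#' phenotype, adjusting for covariates (typically sex). Uses the
#' Frisch-Waugh residualization so the per-variant fits match full
#' `lm(y ~ dosage + covariates)` exactly. Constant-dosage variants are
#' flagged: they get a missing effect and the p = 1 convention.
#'
#' @param genotypes A [genotype_matrix()].
#' @param phenotype Numeric phenotype (no missing values).
#' @param covariates data.frame or vector of covariates; a sex factor is
#'   expanded to a dummy. NULL for no adjustment.
#' @return data.frame of summary statistics: id, chr, pos, effect_allele,
#'   other_allele, beta, se, p, eaf, n, constant.
#' @export
marginal_gwas <- function(genotypes, phenotype, covariates = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  d <- genotypes$dosages
  n <- nrow(d)
  .assert(length(phenotype) == n && !anyNA(phenotype),
          "phenotype must be complete with one value per sample")
  Z <- matrix(1, n, 1)
  if (!is.null(covariates)) {
    cv <- if (is.data.frame(covariates)) covariates else
      data.frame(covariate = covariates)
    mm <- stats::model.matrix(~ ., data = cv)
    Z <- mm  # includes intercept
  }
  q <- qr(Z)
  # sporadic missing dosages are mean-imputed for the scan
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d))
    d[idx] <- mu[((idx - 1) %/% n) + 1]
  }
  yr <- qr.resid(q, phenotype)
  xr <- qr.resid(q, d)
  sxx <- colSums(xr^2)
  constant <- apply(d, 2, function(col) length(unique(col)) == 1L) |
    sxx < 1e-10
  sxy <- colSums(xr * yr)
  beta <- sxy / sxx
  df <- n - ncol(Z) - 1L
  .assert(df > 0, "too few samples for the association scan")
  rss <- sum(yr^2) - beta^2 * sxx
  se <- sqrt(pmax(rss, 0) / df / sxx)
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df)
  beta[constant] <- NA_real_
  se[constant] <- NA_real_
  p[constant] <- 1
  out <- data.frame(
    id = genotypes$variants$id,
    chr = genotypes$variants$chr,
    pos = genotypes$variants$pos,
    effect_allele = genotypes$variants$effect_allele,
    other_allele = genotypes$variants$other_allele,
    beta = beta, se = se, p = p,
    eaf = colMeans(d) / 2, n = n,
    constant = constant,
    stringsAsFactors = FALSE
  )
  if (any(constant)) {
    message(sum(constant), " constant-dosage variant(s) flagged ",
            "(missing effect, p = 1)")
  }
  rownames(out) <- NULL
  out
}

#' @rdname marginal_gwas
#' @param stats Summary-statistics data.frame.
#' @param path File path.
#' @export
write_sumstats_tsv <- function(stats, path) {
  .write_tsv(stats[c("id", "chr", "pos", "effect_allele", "other_allele",
                     "beta", "se", "p", "eaf", "n")], path)
}

#' @rdname marginal_gwas
#' @export
read_sumstats_tsv <- function(path) {
  st <- .read_tsv(path)
  st$chr <- as.character(st$chr)
  st
}

#' Fixed-effect inverse-variance-weighted meta-analysis
#'
#' Combines two sets of summary statistics. Variants are matched by id and
#' harmonized to the effect allele of `a`: a record in `b` with effect and
#' other alleles swapped has its effect sign flipped (and eaf complemented)
#' before combining. Combined effect = sum(beta_i / se_i^2) / sum(1 / se_i^2);
#' combined SE = sqrt(1 / sum(1 / se_i^2)). Variants present in only one
#' input pass through unchanged; variants whose allele pairs match neither
#' orientation are dropped with a message.
#'
#' @param a,b Summary-statistics data.frames as from [marginal_gwas()].
#' @return Combined summary-statistics data.frame.
#' @export
ivw_meta_analysis <- function(a, b) {
  usable <- function(s) !is.na(s$beta) & !is.na(s$se) & s$se > 0
  shared <- intersect(a$id, b$id)
  ia <- match(shared, a$id); ib <- match(shared, b$id)
  same <- a$effect_allele[ia] == b$effect_allele[ib] &
    a$other_allele[ia] == b$other_allele[ib]
  flip <- a$effect_allele[ia] == b$other_allele[ib] &
    a$other_allele[ia] == b$effect_allele[ib]
  bad <- !(same | flip)
  if (any(bad)) {
    message(sum(bad), " variant(s) dropped in meta-analysis: ",
            "irreconcilable allele pairs (",
            paste(utils::head(shared[bad], 5), collapse = ", "),
            if (sum(bad) > 5) ", ..." else "", ")")
  }
  beta_b <- ifelse(flip, -b$beta[ib], b$beta[ib])
  eaf_b <- ifelse(flip, 1 - b$eaf[ib], b$eaf[ib])
  ok <- !bad & usable(a)[ia] & usable(b)[ib]

  out <- a[ia, ]
  w_a <- 1 / a$se[ia]^2
  w_b <- 1 / b$se[ib]^2
  comb_beta <- (w_a * a$beta[ia] + w_b * beta_b) / (w_a + w_b)
  comb_se <- sqrt(1 / (w_a + w_b))
  out$beta[ok] <- comb_beta[ok]
  out$se[ok] <- comb_se[ok]
  out$p[ok] <- 2 * stats::pnorm(-abs(out$beta[ok] / out$se[ok]))
  out$eaf[ok] <- ((w_a * a$eaf[ia] + w_b * eaf_b) / (w_a + w_b))[ok]
  out$n[ok] <- (a$n[ia] + b$n[ib])[ok]
  out <- out[!bad, ]

  only_a <- a[!a$id %in% shared, ]
  only_b <- b[!b$id %in% shared, ]
  res <- rbind(out, only_a, only_b)
  rownames(res) <- NULL
  res
}

#' Clumping parameters
#'
#' @param r2_threshold Squared dosage-correlation threshold in (0, 1];
#'   unselected variants exceeding it near a selected variant are removed.
#' @param window Window half-width, in variant-column positions, within
#'   which correlations are computed.
#' @param p_thresholds Ascending p-value cutoffs in (0, 1]; one candidate
#'   variant set is produced per cutoff.
#' @export
clump_params <- function(r2_threshold = 0.1, window = 250,
                         p_thresholds = c(5e-8, 1e-5, 1e-3, 0.01, 0.05, 0.1, 1)) {
  .assert(.is_prob(r2_threshold, open_left = TRUE), "r2_threshold in (0, 1]")
  .assert(.is_count(window), "window must be a positive integer")
  .assert(length(p_thresholds) >= 1 && all(p_thresholds > 0) &&
            all(p_thresholds <= 1) && !is.unsorted(p_thresholds),
          "p_thresholds must be a nonempty ascending list in (0, 1]")
  structure(list(r2_threshold = r2_threshold, window = as.integer(window),
                 p_thresholds = as.numeric(p_thresholds)),
            class = "clump_params")
}

#' Greedy LD clumping with p-value thresholding
#'
#' Variants are visited in ascending p order (ties broken by variant id);
#' each selected variant removes all not-yet-selected variants whose squared
#' Pearson dosage correlation with it exceeds `r2_threshold` within the
#' window. Each p-value cutoff then keeps its sub-list of the clumped set;
#' weights are the (meta-analytic) effects.
#'
#' @param stats Summary statistics (id, effect_allele, beta, p, ...).
#' @param genotypes Reference [genotype_matrix()] for r-squared computation.
#' @param params A [clump_params()] object.
#' @return Named list, one element per p threshold, each a data.frame
#'   (id, effect_allele, other_allele, weight, p). Empty sets produce a
#'   warning and an empty data.frame.
#' @export
ld_clump_threshold <- function(stats, genotypes, params = clump_params()) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(params, "clump_params"))
  st <- stats[!is.na(stats$beta) & stats$id %in% genotypes$variants$id, ]
  col_of <- match(st$id, colnames(genotypes$dosages))
  ord <- order(st$p, st$id)
  d <- genotypes$dosages
  alive <- rep(TRUE, nrow(st))   # not yet removed
  selected <- logical(nrow(st))
  for (k in ord) {
    if (!alive[k]) next
    selected[k] <- TRUE
    alive[k] <- FALSE
    near <- which(alive & abs(col_of - col_of[k]) <= params$window)
    if (!length(near)) next
    r <- suppressWarnings(
      stats::cor(d[, col_of[k]], d[, col_of[near], drop = FALSE],
                 use = "pairwise.complete.obs"))
    drop <- near[!is.na(r) & r^2 > params$r2_threshold]
    alive[drop] <- FALSE
  }
  kept <- st[selected, ]
  kept <- kept[order(kept$p, kept$id), ]
  out <- lapply(params$p_thresholds, function(pt) {
    sub <- kept[kept$p <= pt,
                c("id", "effect_allele", "other_allele", "beta", "p")]
    names(sub)[names(sub) == "beta"] <- "weight"
    if (nrow(sub) == 0)
      warning("no variants survive p threshold ", pt,
              "; empty score", call. = FALSE)
    rownames(sub) <- NULL
    sub
  })
  names(out) <- paste0("clump_p", format(params$p_thresholds,
                                         scientific = TRUE, digits = 3))
  out
}

# Soft-threshold operator.
.soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

#' LASSO path by cyclic coordinate descent
#'
#' Minimizes `(1/2n) ||y - a - Z c - X b||^2 + lambda * sum(|b|)` over a
#' descending lambda grid with warm starts. Covariates `Z` (typically sex)
#' are unpenalized; predictors are standardized internally and coefficients
#' are reported on the original dosage scale. Convergence requires the
#' maximum absolute coefficient change in a sweep to fall below `tol`.
#'
#' @param genotypes A [genotype_matrix()] or plain dosage matrix (training
#'   samples).
#' @param phenotype Numeric response.
#' @param covariates Unpenalized covariates (vector/data.frame), or NULL.
#' @param lambda_grid Descending positive grid; NULL builds a 20-point
#'   log-spaced grid from the smallest lambda that zeroes every penalized
#'   coefficient down to 1/1000 of it.
#' @param n_lambda,lambda_min_ratio Grid shape when `lambda_grid` is NULL.
#' @param tol Convergence tolerance on coefficient changes (default 1e-6).
#' @param max_sweeps Sweep budget per lambda before erroring (default 1e4).
#' @return Object of class `lasso_path`: `lambda`, `beta` (variants x
#'   lambdas, original scale), `intercept`, `covariate_coef`, `df`
#'   (nonzero count per lambda) and the variant ids.
#' @export
lasso_fit_path <- function(genotypes, phenotype, covariates = NULL,
                           lambda_grid = NULL, n_lambda = 20,
                           lambda_min_ratio = 1e-3,
                           tol = 1e-6, max_sweeps = 1e4) {
  X <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosages else
    genotypes
  ids <- colnames(X)
  y <- phenotype
  n <- nrow(X)
  .assert(length(y) == n && !anyNA(y), "complete phenotype required")
  Z <- matrix(1, n, 1)
  if (!is.null(covariates)) {
    cv <- if (is.data.frame(covariates)) covariates else
      data.frame(covariate = covariates)
    Z <- stats::model.matrix(~ ., data = cv)
  }
  qz <- qr(Z)
  # Unpenalized covariates profile out: solve the lasso on residualized data.
  yr <- qr.resid(qz, y)
  Xr <- qr.resid(qz, X)
  sds <- sqrt(colMeans(Xr^2))     # residualized columns have mean 0
  keep <- sds > 1e-10
  .assert(any(keep), "all predictors are constant after residualization")
  Xs <- sweep(Xr[, keep, drop = FALSE], 2, sds[keep], "/")
  p <- ncol(Xs)
  Xty <- crossprod(Xs, yr)[, 1] / n
  XtX <- crossprod(Xs) / n

  if (is.null(lambda_grid)) {
    lmax <- max(abs(Xty))
    lambda_grid <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                           length.out = n_lambda))
  }
  .assert(all(diff(lambda_grid) < 0) || length(lambda_grid) == 1,
          "lambda grid must be strictly descending")
  .assert(all(lambda_grid >= 0), "lambda values must be non-negative")

  nl <- length(lambda_grid)
  B <- matrix(0, p, nl)
  b <- numeric(p)
  for (li in seq_len(nl)) {
    lam <- lambda_grid[li]
    for (sweep_i in seq_len(max_sweeps)) {
      delta <- 0
      for (j in seq_len(p)) {
        rho <- Xty[j] - sum(XtX[j, ] * b) + b[j]  # diag(XtX) = 1
        bj <- .soft(rho, lam)
        if (bj != b[j]) {
          delta <- max(delta, abs(bj - b[j]))
          b[j] <- bj
        }
      }
      if (delta < tol) break
      if (sweep_i == max_sweeps)
        stop("coordinate descent did not converge at lambda = ", lam,
             call. = FALSE)
    }
    B[, li] <- b
  }
  # back to original dosage scale
  beta <- matrix(0, length(ids), nl,
                 dimnames = list(ids, signif(lambda_grid, 4)))
  beta[keep, ] <- B / sds[keep]
  # covariate block refit per lambda on the unresidualized data
  covcoef <- apply(beta, 2, function(bb) {
    qr.coef(qz, y - X %*% bb)
  })
  covcoef <- matrix(covcoef, ncol = nl,
                    dimnames = list(colnames(Z), colnames(beta)))
  structure(list(lambda = lambda_grid, beta = beta,
                 covariate_coef = covcoef, ids = ids,
                 df = colSums(beta != 0)),
            class = "lasso_path")
}

#' @export
print.lasso_path <- function(x, ...) {
  cat(sprintf("lasso_path: %d lambdas, %d predictors\n",
              length(x$lambda), nrow(x$beta)))
  print(data.frame(lambda = signif(x$lambda, 4), nonzero = x$df,
                   row.names = NULL))
  invisible(x)
}

# Candidate variant sets from a lasso path (one per lambda, dropping empty
# supports and exact duplicates of the previous support).
.lasso_candidates <- function(path, variants) {
  out <- list()
  for (li in seq_along(path$lambda)) {
    nz <- which(path$beta[, li] != 0)
    if (!length(nz)) next
    ids <- path$ids[nz]
    vi <- match(ids, variants$id)
    out[[paste0("lasso_lambda", signif(path$lambda[li], 3))]] <-
      data.frame(id = ids,
                 effect_allele = variants$effect_allele[vi],
                 other_allele = variants$other_allele[vi],
                 weight = unname(path$beta[nz, li]),
                 p = NA_real_,
                 stringsAsFactors = FALSE)
  }
  out
}

#' Select the best candidate score on a held-out split
#'
#' Each candidate variant set is scored on the model-selection samples and
#' ranked by adjusted R-squared of `height ~ score + sex`. Ties go to the
#' candidate with fewer variants, then to the first by name.
#'
#' @param candidates Named list of candidate data.frames
#'   (id, effect_allele, other_allele, weight).
#' @param genotypes [genotype_matrix()] of the selection split (disjoint
#'   from training).
#' @param phenotype,sex Selection-split phenotype and sex.
#' @return List: `model` (a [prs_model()] of the winner), `name`, and
#'   `selection` (per-candidate adjusted R-squared and size).
#' @export
select_model <- function(candidates, genotypes, phenotype, sex) {
  .assert(length(candidates) >= 1, "empty candidate list")
  .assert(!is.null(names(candidates)) && all(nzchar(names(candidates))),
          "candidates must be named")
  sex <- .norm_sex(sex)
  tab <- data.frame(name = names(candidates),
                    n_variants = vapply(candidates, nrow, integer(1)),
                    adj_r2 = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_along(candidates)) {
    cand <- candidates[[k]]
    if (nrow(cand) == 0) next
    vi <- match(cand$id, colnames(genotypes$dosages))
    if (anyNA(vi)) next
    sc <- as.numeric(genotypes$dosages[, vi, drop = FALSE] %*% cand$weight)
    if (stats::sd(sc) < 1e-12) next
    fit <- stats::lm(phenotype ~ sc + sex)
    tab$adj_r2[k] <- summary(fit)$adj.r.squared
  }
  .assert(any(!is.na(tab$adj_r2)),
          "no candidate could be scored on the selection split")
  ord <- order(-tab$adj_r2, tab$n_variants, seq_len(nrow(tab)))
  best <- candidates[[ord[1]]]
  vi <- match(best$id, genotypes$variants$id)
  model <- prs_model(data.frame(
    id = best$id,
    chr = genotypes$variants$chr[vi],
    pos = genotypes$variants$pos[vi],
    effect_allele = best$effect_allele,
    other_allele = best$other_allele,
    effect_weight = best$weight,
    stringsAsFactors = FALSE
  ), name = tab$name[ord[1]])
  list(model = model, name = tab$name[ord[1]], selection = tab)
}

#' Desk-scale score construction pipeline
#'
#' Runs the construction recipe on founder genotypes: the training split is
#' halved into two pseudo-studies whose marginal scans are combined by
#' fixed-effect inverse-variance meta-analysis; candidates come from LD
#' clumping + p-value thresholding of the meta-analysis and from a LASSO
#' path fitted on the full training split; the winner is chosen by adjusted
#' R-squared on the model-selection split. Split fractions default to the
#' proportions of a large biobank training/model-selection/test design
#' (~80/1.5/18.5).
#'
#' @param genotypes Founder [genotype_matrix()].
#' @param phenotype,sex Founder heights (cm) and sex.
#' @param split_fractions Named fractions for train/selection/test,
#'   summing to 1.
#' @param clump A [clump_params()] object.
#' @param lasso_max_variants LASSO arm is fitted on the top variants by
#'   meta-analysis p (desk-scale restriction).
#' @param n_lambda Lambda-grid length for the LASSO arm.
#' @param seed Seed for the split assignment.
#' @return Object of class `prs_construction`: selected `model`, candidate
#'   table, summary statistics, split assignment (`train`/`selection`/
#'   `test` index vectors) and the lasso path.
#' @export
construct_prs <- function(genotypes, phenotype, sex,
                          split_fractions = c(train = 0.80,
                                              selection = 0.015,
                                              test = 0.185),
                          clump = clump_params(),
                          lasso_max_variants = 500,
                          n_lambda = 20,
                          seed = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  split_fractions <- unlist(split_fractions)
  .assert(abs(sum(split_fractions) - 1) < 1e-8 &&
            all(split_fractions > 0) &&
            all(c("train", "selection", "test") %in% names(split_fractions)),
          "split_fractions must name train/selection/test and sum to 1")
  if (!is.null(seed)) set.seed(seed)
  sex <- .norm_sex(sex)
  n <- nrow(genotypes$dosages)
  counts <- floor(n * split_fractions[c("train", "selection", "test")])
  counts[["train"]] <- counts[["train"]] + n - sum(counts)
  .assert(all(counts >= 2), "each split needs at least 2 samples")
  grp <- sample(rep(c("train", "selection", "test"), times = counts))
  idx <- split(seq_len(n), grp)

  sub <- function(ix) genotype_matrix(
    genotypes$dosages[ix, , drop = FALSE], genotypes$variants)

  tr <- idx$train
  half <- seq_len(floor(length(tr) / 2))
  ss_a <- marginal_gwas(sub(tr[half]), phenotype[tr[half]],
                        data.frame(sex = sex[tr[half]]))
  ss_b <- marginal_gwas(sub(tr[-half]), phenotype[tr[-half]],
                        data.frame(sex = sex[tr[-half]]))
  meta <- ivw_meta_analysis(ss_a, ss_b)

  cands <- ld_clump_threshold(meta, sub(tr), clump)
  cands <- cands[vapply(cands, nrow, integer(1)) > 0]

  top <- meta[order(meta$p), ]
  top <- top$id[seq_len(min(lasso_max_variants, nrow(top)))]
  keep_cols <- match(top, colnames(genotypes$dosages))
  path <- lasso_fit_path(genotypes$dosages[tr, keep_cols, drop = FALSE],
                         phenotype[tr], data.frame(sex = sex[tr]),
                         n_lambda = n_lambda)
  cands <- c(cands, .lasso_candidates(path, genotypes$variants))

  sel <- select_model(cands, sub(idx$selection),
                      phenotype[idx$selection], sex[idx$selection])
  structure(list(model = sel$model, name = sel$name,
                 selection = sel$selection, sumstats = meta,
                 lasso = path, splits = idx),
            class = "prs_construction")
}

#' @export
print.prs_construction <- function(x, ...) {
  cat("Polygenic score construction\n")
  cat(sprintf("  selected candidate: %s (%d variants)\n",
              x$name, nrow(x$model$variants)))
  best <- x$selection[order(-x$selection$adj_r2), ]
  print(utils::head(best, 8), row.names = FALSE)
  invisible(x)
}
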