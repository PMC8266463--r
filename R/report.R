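# Assembly of the predictor-comparison report: per (predictor, stratum)
# adjusted R-squared, RMSE, AUROC, AUPRC and odds ratio per SD decrease,
# each with a 95% CI, plus likelihood-ratio tests for declared nested
# predictor pairs.

#' Build an evaluation report for a set of predictors
#'
#' For each predictor and stratum (all / female / male): adjusted
#' R-squared of `height ~ prediction (+ sex in the pooled stratum)`, RMSE
#' of the raw prediction, and — against within-sex short-stature labels —
#' AUROC, AUPRC and the odds ratio per SD decrease of the predicted
#' height. Risk direction: lower predicted height = higher predicted risk.
#' CIs are percentile bootstrap (label-stratified for the discrimination
#' metrics) except the OR, which gets its Wald interval.
#'
#' @param predictions A `prediction_set` from [predict_all()].
#' @param cohort Cohort table with child_id, sex, adult_height_cm.
#' @param rule A [short_stature_rule()].
#' @param lrt_pairs List of 2-vectors of predictor names `c(base, added)`:
#'   each pair tests `height ~ base + sex` against
#'   `height ~ base + added + sex` (e.g. `list(c("mph", "prs"))` asks
#'   whether the score improves on mid-parental height).
#' @param B Bootstrap replicates.
#' @param seed Seed for the bootstrap.
#' @param or_include_sex Include sex in the logistic model of the pooled
#'   stratum.
#' @return Object of class `evaluation_report`: `metrics` data.frame,
#'   `lrt` data.frame, `rule`, `n`.
#' @export
build_report <- function(predictions, cohort, rule = short_stature_rule(),
                         lrt_pairs = list(), B = 2000, seed = 1,
                         or_include_sex = TRUE) {
  .assert(all(c("child_id", "predictor", "predicted_height_cm") %in%
                names(predictions)), "malformed prediction set")
  cohort$sex <- .norm_sex(cohort$sex)
  labels_all <- label_short_stature(cohort$adult_height_cm, cohort$sex, rule)
  names(labels_all) <- cohort$child_id

  preds <- split(predictions, predictions$predictor)
  strata <- c("all", "female", "male")
  rows <- list()
  for (pname in names(preds)) {
    pr <- preds[[pname]]
    ci_idx <- match(pr$child_id, cohort$child_id)
    .assert(!anyNA(ci_idx), "predictions refer to unknown children")
    base <- data.frame(
      obs = cohort$adult_height_cm[ci_idx],
      pred = pr$predicted_height_cm,
      sex = cohort$sex[ci_idx],
      label = labels_all[pr$child_id]
    )
    for (st in strata) {
      d <- if (st == "all") base else base[base$sex == st, , drop = FALSE]
      if (nrow(d) < 10) next
      # seed depends on the stratum only, so identical predictions give
      # identical rows
      rows[[length(rows) + 1L]] <-
        .metric_row(pname, st, d, B, seed + 10L * match(st, strata),
                    or_include_sex = or_include_sex && st == "all")
    }
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL

  lrt <- NULL
  if (length(lrt_pairs)) {
    lrt_rows <- lapply(lrt_pairs, function(pair) {
      .assert(length(pair) == 2, "each lrt pair must name two predictors")
      a <- preds[[pair[1]]]; b <- preds[[pair[2]]]
      .assert(!is.null(a) && !is.null(b),
              paste("lrt pair refers to missing predictor:",
                    paste(pair, collapse = " vs ")))
      shared <- intersect(a$child_id, b$child_id)
      ia <- match(shared, a$child_id); ib <- match(shared, b$child_id)
      ic <- match(shared, cohort$child_id)
      y <- cohort$adult_height_cm[ic]
      sx <- cohort$sex[ic]
      m0 <- stats::lm(y ~ a$predicted_height_cm[ia] + sx)
      m1 <- stats::lm(y ~ a$predicted_height_cm[ia] +
                        b$predicted_height_cm[ib] + sx)
      t <- lrt_nested(m0, m1)
      data.frame(base = pair[1], added = pair[2], n = length(shared),
                 statistic = t$statistic, df = t$df, p = t$p,
                 stringsAsFactors = FALSE)
    })
    lrt <- do.call(rbind, lrt_rows)
    rownames(lrt) <- NULL
  }
  structure(list(metrics = metrics, lrt = lrt, rule = rule,
                 n = nrow(cohort)),
            class = "evaluation_report")
}

.metric_row <- function(pname, stratum, d, B, seed, or_include_sex) {
  n <- nrow(d)
  cases <- sum(d$label)
  # regression metrics
  p_terms <- if (stratum == "all") 2 else 1
  fit <- if (stratum == "all") stats::lm(obs ~ pred + sex, data = d) else
    stats::lm(obs ~ pred, data = d)
  r2_fn <- function(dd) {
    f <- if (stratum == "all") stats::lm(obs ~ pred + sex, data = dd) else
      stats::lm(obs ~ pred, data = dd)
    adjusted_r2(dd$obs, stats::fitted(f), p = p_terms)
  }
  rmse_fn <- function(dd) rmse(dd$obs, dd$pred)
  r2_ci <- bootstrap_ci(r2_fn, d, B = B, seed = seed)
  rmse_ci <- bootstrap_ci(rmse_fn, d, B = B, seed = seed + 1L)

  row <- data.frame(
    predictor = pname, stratum = stratum, n = n, cases = cases,
    adj_r2 = r2_ci$point, adj_r2_low = r2_ci$low, adj_r2_high = r2_ci$high,
    rmse = rmse_ci$point, rmse_low = rmse_ci$low, rmse_high = rmse_ci$high,
    auroc = NA_real_, auroc_low = NA_real_, auroc_high = NA_real_,
    auprc = NA_real_, auprc_low = NA_real_, auprc_high = NA_real_,
    or_per_sd = NA_real_, or_low = NA_real_, or_high = NA_real_,
    stringsAsFactors = FALSE
  )
  if (cases == 0 || cases == n) {
    # a stratum with no (or only) cases carries no discrimination signal
    return(row)
  }
  # risk = lower predicted height, after removing the sex means (the
  # pooled stratum mirrors a discrimination model that includes sex;
  # within one sex this is the identical ranking)
  sex_risk <- function(dd) {
    -stats::ave(dd$pred, dd$sex,
                FUN = function(v) (v - mean(v)) / max(stats::sd(v), 1e-12))
  }
  auroc_fn <- function(dd) auroc(sex_risk(dd), dd$label)
  auprc_fn <- function(dd) auprc(sex_risk(dd), dd$label)
  a_ci <- bootstrap_ci(auroc_fn, d, B = B, seed = seed + 2L,
                       stratify = "label")
  p_ci <- bootstrap_ci(auprc_fn, d, B = B, seed = seed + 3L,
                       stratify = "label")
  row$auroc <- a_ci$point; row$auroc_low <- a_ci$low
  row$auroc_high <- a_ci$high
  row$auprc <- p_ci$point; row$auprc_low <- p_ci$low
  row$auprc_high <- p_ci$high
  # predictor standardized within sex, so the OR is per SD decrease of
  # the sex-adjusted prediction
  z <- stats::ave(d$pred, d$sex,
                  FUN = function(v) (v - mean(v)) / stats::sd(v))
  or <- tryCatch(
    or_per_sd(z, d$label,
              sex = if (or_include_sex) d$sex else NULL),
    error = function(e) NULL)
  if (!is.null(or)) {
    row$or_per_sd <- or$or; row$or_low <- or$ci[1]; row$or_high <- or$ci[2]
  }
  row
}

#' @export
print.evaluation_report <- function(x, digits = 3, ...) {
  cat(sprintf("Evaluation report: %d predictors, %d children\n",
              length(unique(x$metrics$predictor)), x$n))
  m <- x$metrics
  show <- data.frame(
    predictor = m$predictor, stratum = m$stratum, n = m$n, cases = m$cases,
    adj_r2 = round(m$adj_r2, digits), rmse = round(m$rmse, digits),
    auroc = round(m$auroc, digits), auprc = round(m$auprc, digits),
    or_per_sd = round(m$or_per_sd, digits))
  print(show, row.names = FALSE)
  if (!is.null(x$lrt)) {
    cat("\nNested model likelihood-ratio tests:\n")
    print(transform(x$lrt, statistic = round(statistic, 2),
                    p = signif(p, 3)), row.names = FALSE)
  }
  invisible(x)
}

#' Write / read an evaluation report
#'
#' The metric table goes to `<prefix>_metrics.tsv`, the LRT table (when
#' present) to `<prefix>_lrt.tsv`, and the full report to
#' `<prefix>.json`; [read_report()] restores the object from the JSON.
#'
#' @param report An `evaluation_report`.
#' @param prefix Output path prefix.
#' @return Invisibly, the written paths.
#' @export
write_report <- function(report, prefix) {
  stopifnot(inherits(report, "evaluation_report"))
  paths <- c(metrics = paste0(prefix, "_metrics.tsv"),
             json = paste0(prefix, ".json"))
  .write_tsv(report$metrics, paths[["metrics"]])
  if (!is.null(report$lrt)) {
    paths[["lrt"]] <- paste0(prefix, "_lrt.tsv")
    .write_tsv(report$lrt, paths[["lrt"]])
  }
  payload <- list(metrics = report$metrics, lrt = report$lrt,
                  rule = unclass(report$rule), n = report$n)
  jsonlite::write_json(payload, paths[["json"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}

#' @rdname write_report
#' @param path Path to a report JSON written by [write_report()].
#' @export
read_report <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  lrt <- payload$lrt
  if (!is.null(lrt) && !is.data.frame(lrt)) lrt <- as.data.frame(lrt)
  structure(list(
    metrics = as.data.frame(payload$metrics),
    lrt = lrt,
    rule = structure(payload$rule, class = "short_stature_rule"),
    n = payload$n
  ), class = "evaluation_report")
}
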