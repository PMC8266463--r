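# Metric suite: adjusted R-squared, RMSE, the within-sex short-stature
# rule (mean - 2 SD, approximately the shortest 2.3% under normality),
# rank-based AUROC, average-precision AUPRC, logistic odds ratio per SD
# decrease, Gaussian-ML nested likelihood-ratio tests and percentile
# bootstrap confidence intervals.

#' Adjusted R-squared
#'
#' `1 - (1 - R2) (n - 1) / (n - p - 1)` for a fitted linear model with `p`
#' predictors. Supply either observed/predicted values plus `p`, or a
#' fitted `lm`.
#'
#' @param observed,predicted Numeric vectors (fitted values from the
#'   model).
#' @param p Number of predictors in the fitted model (excluding the
#'   intercept).
#' @return Adjusted R-squared.
#' @export
adjusted_r2 <- function(observed, predicted, p = 1) {
  .assert(length(observed) == length(predicted) && length(observed) > 0,
          "observed and predicted must be non-empty and equal length")
  n <- length(observed)
  .assert(n > p + 1, "adjusted R-squared needs n > p + 1")
  rss <- sum((observed - predicted)^2)
  tss <- sum((observed - mean(observed))^2)
  r2 <- 1 - rss / tss
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Root mean square error
#' @param observed,predicted Numeric vectors of equal length.
#' @return RMSE in the units of the inputs (cm for heights).
#' @export
rmse <- function(observed, predicted) {
  .assert(length(observed) == length(predicted) && length(observed) >= 1,
          "observed and predicted must be non-empty and equal length")
  sqrt(mean((observed - predicted)^2))
}

#' Short-stature rule
#'
#' @param sd_multiplier Threshold multiplier (default 2 SDs below the
#'   sex-specific mean, labeling about the shortest 2.3% under normality).
#' @param method `"sd"` (mean - k SD threshold) or `"quantile"` (empirical
#'   tail quantile).
#' @param tail_fraction Tail mass for the quantile method; the default is
#'   the normal mass below -2 SD.
#' @return Object of class `short_stature_rule`.
#' @export
short_stature_rule <- function(sd_multiplier = 2,
                               method = c("sd", "quantile"),
                               tail_fraction = stats::pnorm(-2)) {
  method <- match.arg(method)
  .assert(is.finite(sd_multiplier) && sd_multiplier > 0,
          "sd_multiplier must be positive")
  structure(list(sd_multiplier = sd_multiplier, method = method,
                 tail_fraction = tail_fraction),
            class = "short_stature_rule")
}

#' Label adult short stature within sex
#'
#' Default rule: height strictly below (sex mean - 2 x sex SD), moments
#' taken from the evaluation cohort itself. Alternative mode: the empirical
#' 2.3% tail quantile per sex.
#'
#' @param heights Adult heights (cm).
#' @param sex Sex per individual.
#' @param rule A [short_stature_rule()].
#' @return Logical labels (TRUE = short stature).
#' @export
label_short_stature <- function(heights, sex, rule = short_stature_rule()) {
  stopifnot(inherits(rule, "short_stature_rule"))
  sex <- .norm_sex(sex)
  out <- logical(length(heights))
  for (s in levels(sex)) {
    sel <- sex == s
    if (!any(sel)) next
    h <- heights[sel]
    .assert(length(unique(h)) >= 2,
            paste0("need at least 2 distinct heights for sex ", s))
    thr <- if (rule$method == "sd") {
      sd_s <- stats::sd(h)
      .assert(sd_s > 0, paste0("zero within-sex SD for sex ", s))
      mean(h) - rule$sd_multiplier * sd_s
    } else {
      stats::quantile(h, rule$tail_fraction, names = FALSE, type = 7)
    }
    out[sel] <- h < thr
  }
  out
}

#' AUROC (rank-based Mann-Whitney estimator)
#'
#' Probability that a randomly chosen positive receives a higher score
#' than a randomly chosen negative, ties counted one half. Scores are
#' oriented so that larger values mean higher predicted risk; when scoring
#' predicted heights against short-stature labels, pass the negated
#' heights.
#'
#' @param scores Numeric risk scores.
#' @param labels Logical (or 0/1) class labels; both classes must be
#'   present.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  .assert(length(scores) == length(labels) && !anyNA(labels) &&
            !anyNA(scores), "complete scores and labels required")
  n1 <- sum(labels); n0 <- sum(!labels)
  .assert(n1 > 0 && n0 > 0, "both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUPRC (average precision)
#'
#' Sum over positives, in descending score order, of the precision at each
#' positive's rank, divided by the number of positives. No interpolation
#' between precision-recall points. Ties are resolved conservatively:
#' within a tied score block, positives are placed after negatives.
#'
#' @inheritParams auroc
#' @return Average precision in \[0, 1\]; baseline equals prevalence.
#' @export
auprc <- function(scores, labels) {
  labels <- as.logical(labels)
  .assert(length(scores) == length(labels) && !anyNA(labels) &&
            !anyNA(scores), "complete scores and labels required")
  .assert(any(labels), "at least one positive required")
  ord <- order(-scores, labels)   # within ties: negatives (FALSE) first
  lab <- labels[ord]
  tp <- cumsum(lab)
  prec <- tp / seq_along(lab)
  sum(prec[lab]) / sum(lab)
}

#' Odds ratio per SD decrease of a predictor
#'
#' Maximum-likelihood logistic regression of the label on the standardized
#' predictor (optionally with sex), reporting `exp(-beta)` so that each SD
#' decrease of the predictor confers the printed odds ratio, with a Wald
#' 95% CI. Under complete separation the ML fit diverges; a Firth-type
#' penalized fit is available via `penalized = TRUE`.
#'
#' @param predictor Standardized predictor (SD units).
#' @param labels Logical or 0/1 labels.
#' @param sex Optional sex covariate.
#' @param penalized Use a Firth-style penalized likelihood (needed under
#'   complete separation).
#' @param conf_level Confidence level for the Wald interval.
#' @return List: `or`, `ci` (length 2), `beta`, `se`.
#' @export
or_per_sd <- function(predictor, labels, sex = NULL, penalized = FALSE,
                      conf_level = 0.95) {
  labels <- as.numeric(as.logical(labels))
  .assert(length(unique(labels)) == 2, "both classes must be present")
  X <- cbind(1, predictor)
  if (!is.null(sex)) {
    sex <- .norm_sex(sex)
    X <- cbind(X, as.numeric(sex == "male"))
  }
  if (penalized) {
    fit <- .firth_logistic(X, labels)
    beta <- fit$beta[2]; se <- fit$se[2]
  } else {
    gfit <- suppressWarnings(
      stats::glm.fit(X, labels, family = stats::binomial()))
    beta <- gfit$coefficients[2]
    # Wald SE from the Fisher information at the ML solution
    mu <- gfit$fitted.values
    W <- mu * (1 - mu)
    info <- crossprod(X * sqrt(W))
    cov <- tryCatch(solve(info), error = function(e) NULL)
    se <- if (is.null(cov)) NA_real_ else sqrt(diag(cov))[2]
    if (!is.finite(se) || se > 1e3 || abs(beta) > 30) {
      stop("logistic fit unstable (possible complete separation); ",
           "retry with penalized = TRUE", call. = FALSE)
    }
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  beta <- unname(beta); se <- unname(se)
  ci <- sort(exp(-c(beta + z * se, beta - z * se)))
  list(or = exp(-beta), ci = ci, beta = beta, se = se)
}

# Firth bias-reduced logistic regression by modified Newton scoring.
.firth_logistic <- function(X, y, max_iter = 100, tol = 1e-8) {
  beta <- numeric(ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    mu <- stats::plogis(eta)
    W <- mu * (1 - mu)
    XW <- X * sqrt(W)
    info <- crossprod(XW)
    inv <- solve(info)
    h <- rowSums((XW %*% inv) * XW)
    U <- crossprod(X, y - mu + h * (0.5 - mu))
    step <- inv %*% U
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < tol) break
  }
  eta <- as.numeric(X %*% beta)
  mu <- stats::plogis(eta)
  info <- crossprod(X * sqrt(mu * (1 - mu)))
  list(beta = beta, se = sqrt(diag(solve(info))))
}

#' Likelihood-ratio test for nested linear models
#'
#' Gaussian maximum-likelihood statistic `n log(RSS0 / RSS1)` with degrees
#' of freedom equal to the number of independent columns added, compared to
#' the chi-square upper tail. The small design must lie in the column span
#' of the large one; redundant added columns contribute no degrees of
#' freedom (and no statistic).
#'
#' @param model_small,model_large Fitted `lm` objects on the same rows.
#' @return List: `statistic`, `df`, `p`.
#' @export
lrt_nested <- function(model_small, model_large) {
  Xs <- stats::model.matrix(model_small)
  Xl <- stats::model.matrix(model_large)
  .assert(nrow(Xs) == nrow(Xl), "models must be fitted on the same rows")
  ql <- qr(Xl)
  proj <- qr.resid(ql, Xs)
  .assert(max(abs(proj)) < 1e-6,
          "designs are not nested: small-model columns outside the span")
  df <- ql$rank - qr(Xs)$rank
  n <- nrow(Xs)
  rss0 <- sum(stats::residuals(model_small)^2)
  rss1 <- sum(stats::residuals(model_large)^2)
  stat <- max(n * log(rss0 / rss1), 0)
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}

#' Percentile bootstrap confidence interval
#'
#' Case-resampling percentile interval over `B` replicates; when a
#' `stratify` column is named, resampling is stratified so each replicate
#' preserves the class counts (required for discrimination metrics).
#'
#' @param metric_fn Function of a resampled data.frame returning a scalar.
#' @param data data.frame of cases.
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed; identical seeds give identical endpoints.
#' @param stratify Optional column name to stratify resampling on.
#' @param conf_level Confidence level.
#' @return List: `point`, `low`, `high`, `B`.
#' @export
bootstrap_ci <- function(metric_fn, data, B = 2000, seed = 1,
                         stratify = NULL, conf_level = 0.95) {
  .assert(is.data.frame(data) && nrow(data) >= 2, "need at least 2 cases")
  set.seed(seed)
  point <- metric_fn(data)
  n <- nrow(data)
  strata <- if (is.null(stratify)) rep(1L, n) else
    as.integer(factor(data[[stratify]]))
  by_stratum <- split(seq_len(n), strata)
  vals <- numeric(B)
  for (b in seq_len(B)) {
    idx <- unlist(lapply(by_stratum, function(ix)
      ix[sample.int(length(ix), length(ix), replace = TRUE)]),
      use.names = FALSE)
    vals[b] <- tryCatch(metric_fn(data[idx, , drop = FALSE]),
                        error = function(e) NA_real_)
  }
  bad <- mean(is.na(vals))
  .assert(bad <= 0.01,
          sprintf("metric undefined on %.1f%% of resamples", 100 * bad))
  alpha <- (1 - conf_level) / 2
  qs <- stats::quantile(vals, c(alpha, 1 - alpha), na.rm = TRUE,
                        names = FALSE)
  list(point = point, low = qs[1], high = qs[2], B = B)
}
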