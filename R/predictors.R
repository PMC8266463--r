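# Adult-height predictors: the classical mid-parental (target height)
# formula, the adapted (Swedish regression) mid-parental formula, fitted
# linear combinations of a polygenic score with parental heights, and the
# Khamis-Roche age-specific predictor with a pluggable genetic component.

#' Fixed predictor constants
#'
#' The classical mid-parental offset (6.5 cm, subtracted for girls and
#' added for boys) and the adapted sex-specific regression coefficients
#' (girls: 0.75 x parental mean + 37.85 cm; boys: 0.78 x parental mean +
#' 45.99 cm, from a Swedish population-based fit). Exposed read-only.
#'
#' @return Named list of constants.
#' @export
predictor_constants <- function() {
  list(
    mph_offset_cm = 6.5,
    adapted_girl = c(slope = 0.75, intercept = 37.85),
    adapted_boy = c(slope = 0.78, intercept = 45.99)
  )
}

.check_parent_heights <- function(mother_cm, father_cm) {
  for (h in list(mother_cm, father_cm)) {
    bad <- !is.na(h) & (h <= 100 | h >= 250)
    .assert(!any(bad), "parental heights must lie in (100, 250) cm")
  }
}

#' Classical mid-parental height
#'
#' (mother + father)/2 - 6.5 cm for girls; (mother + father)/2 + 6.5 cm for
#' boys. A missing parent yields NA so callers can fall back to a
#' single-parent or score-based route.
#'
#' @param mother_cm,father_cm Parental heights in cm (vectorized).
#' @param child_sex Sex of the child (female/male codes accepted).
#' @return Predicted adult height in cm.
#' @export
midparental_height <- function(mother_cm, father_cm, child_sex) {
  .check_parent_heights(mother_cm, father_cm)
  sex <- .norm_sex(child_sex)
  off <- predictor_constants()$mph_offset_cm
  (mother_cm + father_cm) / 2 + ifelse(sex == "male", off, -off)
}

#' Adapted mid-parental height
#'
#' Sex-specific affine transform of the parental mean:
#' 0.75 x mean + 37.85 cm for girls, 0.78 x mean + 45.99 cm for boys.
#'
#' @inheritParams midparental_height
#' @return Predicted adult height in cm.
#' @export
adapted_midparental_height <- function(mother_cm, father_cm, child_sex) {
  .check_parent_heights(mother_cm, father_cm)
  sex <- .norm_sex(child_sex)
  k <- predictor_constants()
  pm <- (mother_cm + father_cm) / 2
  ifelse(sex == "male",
         k$adapted_boy[["slope"]] * pm + k$adapted_boy[["intercept"]],
         k$adapted_girl[["slope"]] * pm + k$adapted_girl[["intercept"]])
}

#' Fit a linear predictor combining score and parental components
#'
#' Least-squares fit of adult height on a chosen subset of components
#' (`prs`, `mph`, `mother`, `father`), with sex included unless a component
#' already encodes it (the classical mid-parental height does). Requesting
#' `mph` together with both single parents is refused as rank-deficient by
#' construction.
#'
#' @param data data.frame with columns `adult_height_cm`, `sex`, and the
#'   requested components (`prs` = standardized score, `mph`, `mother`,
#'   `father` in cm).
#' @param components Character subset of `c("prs", "mph", "mother",
#'   "father")`.
#' @param include_sex Add a sex term; default: only when `mph` is not among
#'   the components.
#' @return Object of class `height_predictor` with coef/print/predict
#'   methods. Records the training rows for split-integrity checks.
#' @export
fit_combined_predictor <- function(data,
                                   components,
                                   include_sex = !("mph" %in% components)) {
  .assert(length(components) >= 1 &&
            all(components %in% c("prs", "mph", "mother", "father")),
          "components must be a subset of prs, mph, mother, father")
  .assert(!("mph" %in% components && all(c("mother", "father") %in%
                                           components)),
          "mph together with both single parents is collinear")
  .assert(all(c("adult_height_cm", "sex", components) %in% names(data)),
          "data lacks required columns")
  ok <- stats::complete.cases(data[c("adult_height_cm", components)])
  .assert(sum(ok) > length(components) + 2,
          "every training child must have all requested components")
  rhs <- paste(c(components, if (include_sex) "sex"), collapse = " + ")
  fml <- stats::as.formula(paste("adult_height_cm ~", rhs))
  df <- data[ok, , drop = FALSE]
  df$sex <- .norm_sex(df$sex)
  fit <- stats::lm(fml, data = df)
  .assert(!anyNA(stats::coef(fit)),
          "rank-deficient design: collinear components")
  structure(list(fit = fit, components = components,
                 include_sex = include_sex,
                 training_ids = if ("child_id" %in% names(df)) df$child_id
                 else rownames(df)),
            class = "height_predictor")
}

#' @export
print.height_predictor <- function(x, ...) {
  cat("height_predictor:", paste(x$components, collapse = " + "),
      if (x$include_sex) "+ sex" else "", "\n")
  print(stats::coef(x$fit))
  invisible(x)
}

#' @export
coef.height_predictor <- function(object, ...) stats::coef(object$fit)

#' @export
#' @param object A `height_predictor`.
#' @param newdata data.frame carrying the fitted components (and `sex`).
#' @param ... Unused.
#' @rdname fit_combined_predictor
predict.height_predictor <- function(object, newdata, ...) {
  newdata$sex <- .norm_sex(newdata$sex)
  unname(stats::predict(object$fit, newdata = newdata))
}

#' @export
summary.height_predictor <- function(object, ...) summary(object$fit)

#' @export
residuals.height_predictor <- function(object, ...)
  stats::residuals(object$fit)

# ---------------------------------------------------------------------------
# Khamis-Roche

#' Round an age to the Khamis-Roche half-year grid
#'
#' Nearest half-year; exact quarter-year ties (x.25, x.75) round up.
#' @param age_years Numeric ages.
#' @return Ages on the half-year grid.
#' @export
round_half_year <- function(age_years) {
  floor(age_years * 2 + 0.5) / 2
}

#' Read / write a Khamis-Roche coefficient table
#'
#' TSV columns: `sex`, `age`, `intercept`, `coef_height`, `coef_weight`,
#' `coef_midparent`, one row per (sex, half-year age). The coefficients of
#' the original publication can be transcribed into this format for
#' real-data use; simulation workflows fit an analogous table with
#' [fit_kr_table()].
#'
#' @param path TSV path.
#' @return data.frame (class `kr_table`).
#' @export
read_kr_table <- function(path) {
  tab <- .read_tsv(path)
  need <- c("sex", "age", "intercept", "coef_height", "coef_weight",
            "coef_midparent")
  .assert(all(need %in% names(tab)),
          paste("Khamis-Roche table needs columns:",
                paste(need, collapse = ", ")))
  tab$sex <- .norm_sex(tab$sex)
  .assert(!anyNA(tab[need[-1]]) , "Khamis-Roche table entries must be finite")
  .assert(!anyDuplicated(tab[c("sex", "age")]),
          "duplicate (sex, age) rows in Khamis-Roche table")
  class(tab) <- c("kr_table", "data.frame")
  tab
}

#' @rdname read_kr_table
#' @param table A `kr_table` data.frame.
#' @export
write_kr_table <- function(table, path) .write_tsv(table, path)

#' Fit an age- and sex-specific Khamis-Roche-style coefficient table
#'
#' Per (sex, half-year age): least-squares regression of adult height on
#' current height, current weight and a genetic component (mid-parental
#' height or a calibrated genetic prediction) over the training children.
#' Ages with fewer than `min_n` training children per sex are skipped.
#'
#' @param growth Growth records (child_id, age_years, height_cm, weight_kg).
#' @param cohort Cohort table with child_id, sex, adult_height_cm.
#' @param genetic_component Named numeric (by child_id), the genetic input
#'   the table will expect at prediction time.
#' @param min_n Minimum training children per (sex, age) cell.
#' @return A `kr_table` data.frame.
#' @export
fit_kr_table <- function(growth, cohort, genetic_component, min_n = 30) {
  gi <- match(growth$child_id, cohort$child_id)
  .assert(!anyNA(gi), "growth records refer to unknown children")
  gc <- genetic_component[growth$child_id]
  df <- data.frame(sex = .norm_sex(cohort$sex[gi]),
                   age = round_half_year(growth$age_years),
                   adult = cohort$adult_height_cm[gi],
                   height = growth$height_cm,
                   weight = growth$weight_kg,
                   genetic = as.numeric(gc))
  df <- df[stats::complete.cases(df), ]
  rows <- list()
  for (s in c("female", "male")) {
    for (a in sort(unique(df$age))) {
      cell <- df[df$sex == s & df$age == a, ]
      if (nrow(cell) < min_n) next
      fit <- stats::lm(adult ~ height + weight + genetic, data = cell)
      cf <- stats::coef(fit)
      rows[[length(rows) + 1L]] <- data.frame(
        sex = s, age = a, intercept = cf[["(Intercept)"]],
        coef_height = cf[["height"]], coef_weight = cf[["weight"]],
        coef_midparent = cf[["genetic"]])
    }
  }
  .assert(length(rows) > 0, "no (sex, age) cell had enough training children")
  out <- do.call(rbind, rows)
  out$sex <- .norm_sex(out$sex)
  rownames(out) <- NULL
  class(out) <- c("kr_table", "data.frame")
  out
}

#' Khamis-Roche adult height prediction
#'
#' Age is rounded to the nearest half-year (quarter-year ties round up) and
#' the prediction is the linear form
#' `intercept + c_h * height + c_w * weight + c_m * genetic_component` at
#' the (sex, rounded age) row of the coefficient table. The genetic
#' component is pluggable: classically the mid-parental height, or a
#' genetically predicted height on the same centimeter scale.
#'
#' @param age_years Age in \[8, 17\] (vectorized).
#' @param sex Sex per child.
#' @param current_height_cm,current_weight_kg Childhood measurements.
#' @param genetic_component_cm Mid-parental height or calibrated genetic
#'   prediction (cm).
#' @param table A `kr_table`.
#' @return Predicted adult height in cm.
#' @export
khamis_roche_predict <- function(age_years, sex, current_height_cm,
                                 current_weight_kg, genetic_component_cm,
                                 table) {
  .assert(inherits(table, "kr_table") || is.data.frame(table),
          "table must be a kr_table")
  .assert(all(age_years >= 8 & age_years <= 17),
          "age out of the supported range [8, 17]")
  .assert(all(is.finite(current_height_cm)) &&
            all(is.finite(current_weight_kg)) &&
            all(is.finite(genetic_component_cm)),
          "all Khamis-Roche inputs must be finite")
  sex <- .norm_sex(sex)
  a <- round_half_year(age_years)
  key <- paste(as.character(sex), a)
  tkey <- paste(as.character(table$sex), table$age)
  row <- match(key, tkey)
  if (anyNA(row)) {
    miss <- unique(key[is.na(row)])
    stop("no Khamis-Roche coefficients for (sex, age): ",
         paste(miss, collapse = "; "), call. = FALSE)
  }
  table$intercept[row] + table$coef_height[row] * current_height_cm +
    table$coef_weight[row] * current_weight_kg +
    table$coef_midparent[row] * genetic_component_cm
}

# ---------------------------------------------------------------------------
# Batch prediction

#' Compute every requested predictor for a cohort
#'
#' Known predictor names: `mph`, `adapted_mph`, `mother`, `father`, `prs`
#' (calibrated genetic prediction in cm), `kr_mph`, `kr_prs` (Khamis-Roche
#' at a given age with the mid-parental or genetic component), and fitted
#' combinations `prs+mph`, `prs+mother`, `prs+father`. Children lacking an
#' input are excluded for that predictor and counted in the coverage
#' attribute.
#'
#' @param cohort Cohort table (child_id, sex, adult_height_cm, parental
#'   heights).
#' @param predictors Character vector of predictor names.
#' @param prs_cm Named numeric by child_id: calibrated genetic prediction
#'   (cm). Required for `prs`, `kr_prs` and combinations.
#' @param growth Growth records; required for `kr_*` predictors.
#' @param kr_table A `kr_table`; required for `kr_*` predictors.
#' @param kr_age Half-year age at which Khamis-Roche predictions are taken.
#' @param fitted Named list of `height_predictor` objects for the
#'   combination predictors (names like `"prs+mph"`); fitted on a training
#'   split by the caller.
#' @return data.frame (`prediction_set`): child_id, predictor,
#'   predicted_height_cm; with a `coverage` attribute of per-predictor
#'   counts.
#' @export
predict_all <- function(cohort, predictors, prs_cm = NULL, growth = NULL,
                        kr_table = NULL, kr_age = 10, fitted = list()) {
  known <- c("mph", "adapted_mph", "mother", "father", "prs",
             "kr_mph", "kr_prs", "prs+mph", "prs+mother", "prs+father")
  bad <- setdiff(predictors, known)
  .assert(length(bad) == 0,
          paste("unknown predictor name(s):", paste(bad, collapse = ", ")))
  sex <- .norm_sex(cohort$sex)
  n <- nrow(cohort)
  get_prs <- function() {
    .assert(!is.null(prs_cm), "prs_cm required for score-based predictors")
    as.numeric(prs_cm[cohort$child_id])
  }
  get_growth_at <- function(age) {
    .assert(!is.null(growth), "growth records required for kr_* predictors")
    g <- growth[round_half_year(growth$age_years) == age, ]
    g[match(cohort$child_id, g$child_id), c("height_cm", "weight_kg")]
  }
  one <- function(name) {
    pred <- switch(name,
      mph = midparental_height(cohort$mother_height_cm,
                               cohort$father_height_cm, sex),
      adapted_mph = adapted_midparental_height(cohort$mother_height_cm,
                                               cohort$father_height_cm, sex),
      mother = {
        hp <- fitted[["mother"]]
        nd <- data.frame(mother = cohort$mother_height_cm, sex = sex)
        if (is.null(hp)) cohort$mother_height_cm else {
          out <- rep(NA_real_, n)
          ok <- !is.na(nd$mother)
          out[ok] <- predict(hp, nd[ok, , drop = FALSE]); out
        }
      },
      father = {
        hp <- fitted[["father"]]
        nd <- data.frame(father = cohort$father_height_cm, sex = sex)
        if (is.null(hp)) cohort$father_height_cm else {
          out <- rep(NA_real_, n)
          ok <- !is.na(nd$father)
          out[ok] <- predict(hp, nd[ok, , drop = FALSE]); out
        }
      },
      prs = get_prs(),
      kr_mph = {
        gw <- get_growth_at(kr_age)
        mph <- midparental_height(cohort$mother_height_cm,
                                  cohort$father_height_cm, sex)
        ok <- stats::complete.cases(gw) & !is.na(mph)
        out <- rep(NA_real_, n)
        out[ok] <- khamis_roche_predict(rep(kr_age, sum(ok)), sex[ok],
                                        gw$height_cm[ok], gw$weight_kg[ok],
                                        mph[ok], kr_table)
        out
      },
      kr_prs = {
        gw <- get_growth_at(kr_age)
        ps <- get_prs()
        ok <- stats::complete.cases(gw) & !is.na(ps)
        out <- rep(NA_real_, n)
        out[ok] <- khamis_roche_predict(rep(kr_age, sum(ok)), sex[ok],
                                        gw$height_cm[ok], gw$weight_kg[ok],
                                        ps[ok], kr_table)
        out
      },
      {
        hp <- fitted[[name]]
        .assert(!is.null(hp),
                paste0("no fitted predictor supplied for '", name, "'"))
        nd <- data.frame(sex = sex,
                         prs = get_prs(),
                         mph = midparental_height(cohort$mother_height_cm,
                                                  cohort$father_height_cm,
                                                  sex),
                         mother = cohort$mother_height_cm,
                         father = cohort$father_height_cm)
        ok <- stats::complete.cases(nd[hp$components])
        out <- rep(NA_real_, n)
        out[ok] <- predict(hp, nd[ok, , drop = FALSE])
        out
      })
    pred
  }
  rows <- lapply(predictors, function(nm) {
    data.frame(child_id = cohort$child_id, predictor = nm,
               predicted_height_cm = one(nm), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[!is.na(out$predicted_height_cm), ]
  rownames(out) <- NULL
  cov <- table(factor(out$predictor, levels = predictors))
  attr(out, "coverage") <- stats::setNames(as.integer(cov), names(cov))
  class(out) <- c("prediction_set", "data.frame")
  out
}

#' @rdname predict_all
#' @param predictions A `prediction_set`.
#' @param path TSV path.
#' @export
write_predictions_tsv <- function(predictions, path) {
  .write_tsv(as.data.frame(predictions), path)
}

#' @rdname predict_all
#' @export
read_predictions_tsv <- function(path) {
  out <- .read_tsv(path)
  class(out) <- c("prediction_set", "data.frame")
  out
}
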