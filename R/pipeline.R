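# Config-driven orchestration: simulate -> construct or load a score ->
# harmonize/score/calibrate -> predict -> evaluate -> report, with every
# random draw routed through seeds derived from the config and a manifest
# of file digests for reproducibility checks.

#' Build and validate an experiment configuration
#'
#' Either pass a YAML/JSON file path or a nested list. Exactly one of the
#' `construction` block and `scoring_file` may be active. Missing blocks
#' get package defaults.
#'
#' @param config Path to a YAML/JSON config, or a list with elements
#'   `simulation` (arguments of [sim_params()]), `construction` (arguments
#'   of [construct_prs()] minus data) or `scoring_file`, `predictors`
#'   (character), `evaluation` (`bootstrap_B`, `seed`, `sd_multiplier`,
#'   `lrt_pairs`), `kr` (`age`, `fit_fraction`), `output_dir`, `seed`.
#' @return Validated config (class `experiment_config`).
#' @export
experiment_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE) else
        yaml::read_yaml(config)
  }
  .assert(is.list(config), "config must be a list or a YAML/JSON path")
  .assert(!(length(config$construction) > 0 &&
              length(config$scoring_file) > 0),
          "exactly one of construction block and scoring_file may be active")
  defaults <- list(
    simulation = list(),
    construction = list(),
    scoring_file = NULL,
    predictors = c("mph", "adapted_mph", "prs", "mother", "father",
                   "prs+mph", "prs+mother", "prs+father"),
    evaluation = list(bootstrap_B = 500, seed = 104729, sd_multiplier = 2,
                      lrt_pairs = list(c("mph", "prs"), c("prs", "mph"))),
    kr = list(age = 10, fit_fraction = 0.5),
    output_dir = NULL,
    seed = 1L
  )
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  if (is.null(cfg$scoring_file) && length(cfg$construction) == 0) {
    cfg$construction <- list()   # construct by default
  }
  cfg$evaluation$lrt_pairs <- lapply(cfg$evaluation$lrt_pairs, unlist)
  # YAML/JSON round-trips turn named vectors into lists; normalize
  if (!is.null(cfg$construction$split_fractions)) {
    sf <- unlist(cfg$construction$split_fractions)
    if (is.null(names(sf)) && length(sf) == 3)
      names(sf) <- c("train", "selection", "test")
    cfg$construction$split_fractions <- sf
  }
  cl <- cfg$construction$clump
  if (!is.null(cl) && !inherits(cl, "clump_params")) {
    defaults_cl <- clump_params()
    cfg$construction$clump <- clump_params(
      r2_threshold = cl$r2_threshold %||% defaults_cl$r2_threshold,
      window = cl$window %||% defaults_cl$window,
      p_thresholds = unlist(cl$p_thresholds) %||% defaults_cl$p_thresholds)
  }
  structure(cfg, class = "experiment_config")
}

#' Run the full experiment described by a configuration
#'
#' Stages, in order: simulate the trio cohort (with growth records when any
#' Khamis-Roche predictor is requested); construct a score on the founders
#' (or load an external scoring file); harmonize and score the children;
#' calibrate the standardized score to centimeters on the founder test
#' split; fit any requested combination predictors; predict; evaluate.
#' When `output_dir` is set, every artifact is written (TSV/VCF/JSON) and a
#' run manifest with MD5 digests, stage wall times and the seed registry is
#' produced; re-running an unchanged config reproduces identical digests.
#'
#' @param config An [experiment_config()] (or anything it accepts).
#' @return List (class `experiment_run`): `sim`, `model`, `harmonization`,
#'   `scores`, `calibration`, `predictions`, `report`, `manifest`.
#' @export
run_experiment <- function(config = experiment_config()) {
  cfg <- if (inherits(config, "experiment_config")) config else
    experiment_config(config)
  t_stage <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- expr
    list(value = val, secs = proc.time()[["elapsed"]] - t0)
  }
  times <- list(); seeds <- list()
  stage <- function(name, fn) {
    res <- tryCatch(t_stage(fn()), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    times[[name]] <<- res$secs
    res$value
  }

  need_growth <- any(grepl("^kr_", cfg$predictors))
  seeds$simulation <- cfg$seed
  sim <- stage("simulate", function() {
    params <- do.call(sim_params, c(cfg$simulation,
                                    list(seed = seeds$simulation)))
    simulate_trio_cohort(params, growth = need_growth)
  })
  co <- sim$cohort

  founder_ids <- c(co$mother_id, co$father_id)
  founder_height <- c(co$mother_height_cm, co$father_height_cm)
  founder_sex <- rep(c("female", "male"), each = nrow(co))

  if (is.null(cfg$scoring_file)) {
    seeds$construction <- cfg$seed + 1L
    built <- stage("construct", function() {
      fg <- genotype_matrix(
        sim$genotypes$dosages[founder_ids, , drop = FALSE],
        sim$genotypes$variants)
      do.call(construct_prs,
              c(list(genotypes = fg, phenotype = founder_height,
                     sex = founder_sex, seed = seeds$construction),
                cfg$construction))
    })
    model <- built$model
    calib_ids <- founder_ids[built$splits$test]
  } else {
    built <- NULL
    model <- stage("load_score", function()
      read_scoring_file(cfg$scoring_file))
    calib_ids <- founder_ids
  }

  scored <- stage("score", function() {
    harm <- harmonize_variants(model, sim$genotypes)
    sc <- compute_scores(harm, sim$genotypes)
    # standardize against the child cohort (the evaluation population)
    sc <- standardize_scores(sc, reference = co$child_id)
    list(harmonization = harm, scores = sc)
  })
  scores <- scored$scores

  calibration <- stage("calibrate", function() {
    all_sex <- c(co$sex, founder_sex)[match(scores$sample_id,
                                            c(co$child_id, founder_ids))]
    all_height <- c(co$adult_height_cm, founder_height)[
      match(scores$sample_id, c(co$child_id, founder_ids))]
    calibrate_to_cm(scores, all_height, all_sex, training = calib_ids)
  })

  child_std <- scores$std_score[match(co$child_id, scores$sample_id)]
  prs_cm <- stats::setNames(
    predict(calibration, child_std, co$sex), co$child_id)

  predictions <- stage("predict", function() {
    combos <- intersect(cfg$predictors,
                        c("prs+mph", "prs+mother", "prs+father"))
    fitted <- list()
    if (length(combos)) {
      df <- data.frame(child_id = co$child_id, sex = co$sex,
                       adult_height_cm = co$adult_height_cm,
                       prs = unname(prs_cm),
                       mph = midparental_height(co$mother_height_cm,
                                                co$father_height_cm, co$sex),
                       mother = co$mother_height_cm,
                       father = co$father_height_cm)
      for (cb in combos) {
        comps <- strsplit(cb, "+", fixed = TRUE)[[1]]
        fitted[[cb]] <- fit_combined_predictor(df, comps)
      }
    }
    kr_tab <- NULL
    if (need_growth) {
      kr_tab <- fit_kr_table(sim$growth, co,
                             stats::setNames(
                               midparental_height(co$mother_height_cm,
                                                  co$father_height_cm,
                                                  co$sex), co$child_id))
    }
    predict_all(co, cfg$predictors, prs_cm = prs_cm, growth = sim$growth,
                kr_table = kr_tab, kr_age = cfg$kr$age, fitted = fitted)
  })

  seeds$evaluation <- cfg$evaluation$seed
  report <- stage("evaluate", function() {
    pairs <- Filter(function(p) all(p %in% cfg$predictors),
                    cfg$evaluation$lrt_pairs)
    build_report(predictions, co,
                 rule = short_stature_rule(cfg$evaluation$sd_multiplier),
                 lrt_pairs = pairs, B = cfg$evaluation$bootstrap_B,
                 seed = seeds$evaluation)
  })

  manifest <- NULL
  if (!is.null(cfg$output_dir)) {
    dir <- cfg$output_dir
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- write_cohort(sim, dir)
    write_scoring_file(model, file.path(dir, "score.txt"))
    write_scores_tsv(scores, file.path(dir, "scores.tsv"))
    write_predictions_tsv(predictions, file.path(dir, "predictions.tsv"))
    rep_paths <- write_report(report, file.path(dir, "report"))
    paths <- c(paths, score = file.path(dir, "score.txt"),
               scores = file.path(dir, "scores.tsv"),
               predictions = file.path(dir, "predictions.tsv"), rep_paths)
    # hash the scientific configuration, not where it was written
    cfg_hashable <- unclass(cfg)
    cfg_hashable$output_dir <- NULL
    cfg_json <- jsonlite::toJSON(.strip_classes(cfg_hashable),
                                 auto_unbox = TRUE, digits = NA,
                                 null = "null")
    manifest <- list(
      config_md5 = .md5_string(cfg_json),
      package_version = as.character(utils::packageVersion("statureprs")),
      seeds = seeds,
      stage_seconds = times,
      files = as.list(tools::md5sum(unname(paths)))
    )
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(list(sim = sim, construction = built, model = model,
                 harmonization = scored$harmonization, scores = scores,
                 calibration = calibration, predictions = predictions,
                 report = report, manifest = manifest, config = cfg,
                 stage_seconds = times),
            class = "experiment_run")
}

.strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), .strip_classes) else unclass(x)
}

.md5_string <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(x), tf)
  unname(tools::md5sum(tf))
}

#' @export
print.experiment_run <- function(x, ...) {
  cat("experiment_run\n")
  print(x$sim)
  if (!is.null(x$model))
    cat(sprintf("  score: %s (%d variants)\n", x$model$metadata$name,
                nrow(x$model$variants)))
  print(x$report)
  invisible(x)
}

#' Predictor comparison with per-age Khamis-Roche curves
#'
#' Reproduces the experiment's two headline exhibits on the synthetic
#' cohort: the predictor-by-stratum metric table, and per-age
#' Khamis-Roche performance curves. Children are split once into a
#' table-fitting half (used to fit the age- and sex-specific Khamis-Roche
#' coefficients) and an evaluation half; ages at which either sex has
#' fewer than `min_per_sex` evaluation children are dropped with a
#' warning.
#'
#' @param config An [experiment_config()]; Khamis-Roche predictors are
#'   forced on and growth records simulated.
#' @param min_per_sex Retention rule for the age curve.
#' @return List (class `paper_comparison`): `age_curves` (age, predictor,
#'   adj_r2, rmse, n), `report`, `run`.
#' @export
run_paper_style_comparison <- function(config = experiment_config(),
                                       min_per_sex = 50) {
  cfg <- if (inherits(config, "experiment_config")) config else
    experiment_config(config)
  cfg$predictors <- union(cfg$predictors, c("mph", "prs", "kr_mph", "kr_prs"))
  run <- run_experiment(cfg)
  sim <- run$sim
  co <- sim$cohort
  prs_cm <- stats::setNames(
    predict(run$calibration,
            run$scores$std_score[match(co$child_id,
                                       run$scores$sample_id)], co$sex),
    co$child_id)
  mph <- stats::setNames(
    midparental_height(co$mother_height_cm, co$father_height_cm, co$sex),
    co$child_id)

  set.seed(cfg$seed + 7L)
  fit_half <- sample(co$child_id,
                     floor(nrow(co) * cfg$kr$fit_fraction))
  eval_half <- setdiff(co$child_id, fit_half)
  growth_fit <- sim$growth[sim$growth$child_id %in% fit_half, ]
  kr_tab <- fit_kr_table(growth_fit, co, mph)

  ages <- sort(unique(round_half_year(sim$growth$age_years)))
  curves <- list()
  for (a in ages) {
    g <- sim$growth[round_half_year(sim$growth$age_years) == a &
                      sim$growth$child_id %in% eval_half, ]
    ci <- match(g$child_id, co$child_id)
    sex_a <- co$sex[ci]
    if (min(table(.norm_sex(sex_a))) < min_per_sex) {
      warning("age ", a, " dropped: fewer than ", min_per_sex,
              " evaluation children in one sex", call. = FALSE)
      next
    }
    has_row <- paste(as.character(.norm_sex(sex_a)), a) %in%
      paste(as.character(kr_tab$sex), kr_tab$age)
    for (which_g in c("kr_mph", "kr_prs")) {
      gc <- if (which_g == "kr_mph") mph[g$child_id] else prs_cm[g$child_id]
      ok <- has_row & !is.na(gc)
      if (sum(ok) < 10) next
      pred <- khamis_roche_predict(rep(a, sum(ok)), sex_a[ok],
                                   g$height_cm[ok], g$weight_kg[ok],
                                   gc[ok], kr_tab)
      obs <- co$adult_height_cm[ci][ok]
      fit <- stats::lm(obs ~ pred + .norm_sex(sex_a[ok]))
      curves[[length(curves) + 1L]] <- data.frame(
        age = a, predictor = which_g,
        adj_r2 = adjusted_r2(obs, stats::fitted(fit), p = 2),
        rmse = rmse(obs, pred), n = sum(ok))
    }
  }
  age_curves <- do.call(rbind, curves)
  rownames(age_curves) <- NULL
  structure(list(age_curves = age_curves, report = run$report, run = run),
            class = "paper_comparison")
}

#' @export
print.paper_comparison <- function(x, ...) {
  cat("Khamis-Roche age curves (evaluation half):\n")
  print(transform(x$age_curves, adj_r2 = round(adj_r2, 3),
                  rmse = round(rmse, 2)), row.names = FALSE)
  cat("\n")
  print(x$report)
  invisible(x)
}
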