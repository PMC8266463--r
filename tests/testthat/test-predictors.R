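# Mid-parental formulas, combined predictors, Khamis-Roche.

test_that("classical mid-parental height matches the printed formula", {
  expect_equal(midparental_height(160, 173, "female"), 160.0)
  expect_equal(midparental_height(160, 173, "male"), 173.0)
  expect_equal(midparental_height(170, 170, "female"), 163.5)
  # sex symmetry: identical parents differ by exactly 13 cm
  expect_equal(midparental_height(165, 180, "male") -
                 midparental_height(165, 180, "female"), 13.0)
  # missing parent signals absence
  expect_true(is.na(midparental_height(NA, 180, "female")))
  expect_error(midparental_height(90, 180, "female"), "\\(100, 250\\)")
})

test_that("adapted mid-parental height uses the sex-specific affine form", {
  expect_equal(adapted_midparental_height(164, 164, "female"), 160.85)
  expect_equal(adapted_midparental_height(178, 178, "male"), 184.83)
  # girls' slope on the parental mean is 0.75
  pm <- seq(150, 180, by = 5)
  out <- adapted_midparental_height(pm, pm, rep("female", length(pm)))
  expect_equal(unique(round(diff(out) / diff(pm), 10)), 0.75)
  k <- predictor_constants()
  expect_equal(k$mph_offset_cm, 6.5)
  expect_equal(unname(k$adapted_boy), c(0.78, 45.99))
})

test_that("combined predictors nest and refuse collinear components", {
  sim <- small_sim()
  co <- sim$cohort
  set.seed(40)
  df <- data.frame(child_id = co$child_id, sex = co$sex,
                   adult_height_cm = co$adult_height_cm,
                   prs = co$true_genetic_value_cm +
                     rnorm(nrow(co), 0, 2),
                   mph = midparental_height(co$mother_height_cm,
                                            co$father_height_cm, co$sex),
                   mother = co$mother_height_cm,
                   father = co$father_height_cm)
  r2 <- function(fit) summary(fit$fit)$r.squared
  f_mph <- fit_combined_predictor(df, "mph")
  f_prs <- fit_combined_predictor(df, "prs")
  # sex included so both single-component designs nest inside
  f_both <- fit_combined_predictor(df, c("prs", "mph"), include_sex = TRUE)
  expect_gte(r2(f_both), max(r2(f_mph), r2(f_prs)))
  # mph already encodes sex: default leaves it out; single slope near 1
  expect_false(f_mph$include_sex)
  expect_equal(unname(coef(f_mph)["mph"]), 1, tolerance = 0.15)
  expect_error(fit_combined_predictor(df, c("mph", "mother", "father")),
               "collinear")
  expect_error(fit_combined_predictor(df, "bogus"), "subset")
  # predictions apply to new children with the same components
  pred <- predict(f_both, df[1:10, ])
  expect_length(pred, 10)
  expect_true(all(is.finite(pred)))
})

test_that("overfitting check: a noise component moves training R2 only", {
  sim <- small_sim()
  co <- sim$cohort
  set.seed(41)
  df <- data.frame(sex = co$sex, adult_height_cm = co$adult_height_cm,
                   mph = midparental_height(co$mother_height_cm,
                                            co$father_height_cm, co$sex),
                   prs = rnorm(nrow(co)))   # pure noise labelled prs
  train <- seq_len(250); test <- setdiff(seq_len(nrow(co)), train)
  f0 <- fit_combined_predictor(df[train, ], "mph")
  f1 <- fit_combined_predictor(df[train, ], c("mph", "prs"),
                               include_sex = FALSE)
  sse <- function(f, d) mean((d$adult_height_cm - predict(f, d))^2)
  expect_gte(sse(f0, df[train, ]), sse(f1, df[train, ]))   # training improves
  expect_lt(abs(sse(f1, df[test, ]) - sse(f0, df[test, ])) /
              sse(f0, df[test, ]), 0.05)                   # test within noise
})

test_that("half-year rounding follows the ties-up contract", {
  expect_equal(round_half_year(10.74), 10.5)
  expect_equal(round_half_year(10.76), 11.0)
  expect_equal(round_half_year(10.25), 10.5)
  expect_equal(round_half_year(10.75), 11.0)
  expect_equal(round_half_year(c(8, 8.2, 16.9)), c(8, 8, 17))
})

test_that("Khamis-Roche prediction is the tabulated linear form", {
  tab <- data.frame(sex = c("male", "male", "female"),
                    age = c(10.5, 11, 10.5),
                    intercept = c(10, 0, 5),
                    coef_height = c(0.8, 1, 0.9),
                    coef_weight = c(0.1, 0, 0.2),
                    coef_midparent = c(0.2, 0, 0.1))
  tab$sex <- factor(tab$sex, levels = c("female", "male"))
  class(tab) <- c("kr_table", "data.frame")
  # hand-evaluated synthetic row
  expect_equal(khamis_roche_predict(10.5, "male", 140, 35, 165, tab),
               10 + 0.8 * 140 + 0.1 * 35 + 0.2 * 165)
  # identity row returns current height
  expect_equal(khamis_roche_predict(11, "male", 148.3, 40, 170, tab), 148.3)
  # age rounding picks the right coefficient row
  expect_equal(khamis_roche_predict(10.74, "male", 140, 35, 165, tab),
               khamis_roche_predict(10.5, "male", 140, 35, 165, tab))
  expect_equal(khamis_roche_predict(10.76, "male", 148.3, 40, 170, tab),
               148.3)
  # missing (sex, age) row and out-of-range age are refused by name
  expect_error(khamis_roche_predict(12, "male", 140, 35, 165, tab),
               "male 12")
  expect_error(khamis_roche_predict(7.9, "male", 140, 35, 165, tab),
               "\\[8, 17\\]")
  # genetic component is a pure plug-in: equal inputs, equal outputs
  expect_equal(khamis_roche_predict(10.5, "female", 139, 33, 162.2, tab),
               khamis_roche_predict(10.5, "female", 139, 33, 162.2, tab))
})

test_that("Khamis-Roche tables round-trip and validate", {
  sim <- small_sim()
  co <- sim$cohort
  mph <- setNames(midparental_height(co$mother_height_cm,
                                     co$father_height_cm, co$sex),
                  co$child_id)
  tab <- fit_kr_table(sim$growth, co, mph)
  expect_true(all(c("intercept", "coef_height", "coef_midparent") %in%
                    names(tab)))
  dir <- withr::local_tempdir()
  f <- file.path(dir, "kr.tsv")
  write_kr_table(tab, f)
  back <- read_kr_table(f)
  expect_equal(back$intercept, tab$intercept, tolerance = 1e-9)
  expect_identical(as.character(back$sex), as.character(tab$sex))
})

test_that("predict_all covers availability accounting and determinism", {
  sim <- small_sim()
  co <- sim$cohort
  prs_cm <- setNames(co$true_genetic_value_cm +
                       sim$params$sex_means[as.character(co$sex)],
                     co$child_id)
  # no parental heights: mph coverage 0, prs coverage full
  co_orphan <- co
  co_orphan$mother_height_cm <- NA_real_
  co_orphan$father_height_cm <- NA_real_
  ps <- predict_all(co_orphan, c("mph", "prs"), prs_cm = prs_cm)
  cov <- attr(ps, "coverage")
  expect_equal(unname(cov["mph"]), 0L)
  expect_equal(unname(cov["prs"]), nrow(co))
  # determinism
  ps1 <- predict_all(co, c("mph", "adapted_mph", "prs"), prs_cm = prs_cm)
  ps2 <- predict_all(co, c("mph", "adapted_mph", "prs"), prs_cm = prs_cm)
  expect_identical(ps1, ps2)
  # both mid-parental variants are affine in the parental mean
  wide <- split(ps1$predicted_height_cm, ps1$predictor)
  expect_gt(cor(wide$mph, wide$adapted_mph), 0.99)
  expect_error(predict_all(co, "nope"), "unknown predictor")
})
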