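# Scoring-file parsing, allele harmonization, score computation,
# standardization and calibration.

test_that("scoring files parse in both dialects and write back", {
  dir <- withr::local_tempdir()
  f1 <- write_toy_scoring_file(file.path(dir, "a.txt"), rsid = TRUE)
  m1 <- read_scoring_file(f1)
  expect_equal(length(m1), 2)
  expect_equal(m1$variants$effect_weight, c(0.25, -0.10))
  expect_equal(m1$metadata$name, "toy_score")
  f2 <- write_toy_scoring_file(file.path(dir, "b.txt"), rsid = FALSE)
  m2 <- read_scoring_file(f2)
  expect_equal(m2$variants$id, c("1:100", "2:200"))
  # writer emits the same dialect and round-trips
  f3 <- file.path(dir, "c.txt")
  write_scoring_file(m1, f3)
  m3 <- read_scoring_file(f3)
  expect_equal(m3$variants$effect_weight, m1$variants$effect_weight)
  expect_identical(m3$variants$id, m1$variants$id)
})

test_that("malformed scoring files fail with informative errors", {
  dir <- withr::local_tempdir()
  # missing effect_weight column
  f <- file.path(dir, "bad1.txt")
  writeLines(c("rsID\teffect_allele", "rs1\tA"), f)
  expect_error(read_scoring_file(f), "effect_weight")
  # non-numeric weight names the row
  f2 <- file.path(dir, "bad2.txt")
  writeLines(c("rsID\teffect_allele\teffect_weight",
               "rs1\tA\t0.5", "rs2\tG\toops"), f2)
  expect_error(read_scoring_file(f2), "row 2")
  # duplicate ids are listed
  f3 <- file.path(dir, "bad3.txt")
  writeLines(c("rsID\teffect_allele\teffect_weight",
               "rs1\tA\t0.5", "rs1\tG\t0.2"), f3)
  expect_error(read_scoring_file(f3), "rs1")
})

test_that("harmonization keeps, flips and discards correctly", {
  g <- tiny_panel(matrix(c(0, 1, 2, 2, 1, 0, 1, 1, 1), 3, 3),
                  effect = c("A", "C", "T"), other = c("G", "T", "A"))
  mod <- prs_model(data.frame(
    id = c("rs001", "rs002", "rs003", "rs_absent", "rs005"),
    effect_allele = c("A", "T", "C", "A", "G"),
    other_allele = c("G", "C", "G", "G", "T"),
    effect_weight = c(0.5, 1, 1, 1, 1), stringsAsFactors = FALSE))
  h <- harmonize_variants(mod, g)
  r <- h$report
  expect_equal(r$kept, 1)       # rs001 exact match
  expect_equal(r$flipped, 1)    # rs002 swapped orientation
  expect_equal(r$discarded, 3)  # rs003 inconsistent, rs_absent, rs005
  expect_equal(r$kept + r$flipped + r$discarded, r$total)
  expect_true(h$model$variants$flip[h$model$variants$id == "rs002"])
  # flipped dosage contributes w * (2 - d)
  s <- compute_scores(h, g)
  manual <- 0.5 * g$dosages[, "rs001"] + 1 * (2 - g$dosages[, "rs002"])
  expect_equal(s$raw_score, unname(manual))
})

test_that("discard accounting holds on randomized harmonization cases", {
  set.seed(31)
  bases <- c("A", "C", "G", "T")
  for (rep_i in 1:20) {
    L <- sample(3:12, 1)
    ea <- sample(bases, L, replace = TRUE)
    oa <- vapply(ea, function(b) sample(setdiff(bases, b), 1), "")
    g <- tiny_panel(matrix(rbinom(4 * L, 2, 0.5), 4, L),
                    effect = ea, other = oa)
    # model: random subset present, random orientation, some absent
    take <- sample(L, sample(L, 1))
    flip <- sample(c(TRUE, FALSE), length(take), replace = TRUE)
    mod_df <- data.frame(
      id = c(colnames(g$dosages)[take],
             sprintf("rs_missing%02d", seq_len(3))),
      effect_allele = c(ifelse(flip, oa[take], ea[take]), "A", "A", "A"),
      other_allele = c(ifelse(flip, ea[take], oa[take]), "G", "G", "G"),
      effect_weight = 1, stringsAsFactors = FALSE)
    h <- harmonize_variants(prs_model(mod_df), g)
    r <- h$report
    expect_equal(r$kept + r$flipped + r$discarded, nrow(mod_df))
    expect_equal(r$discarded, 3)
    expect_equal(r$flipped, sum(flip & ea[take] != oa[take]))
  }
})

test_that("scores match a brute-force double loop and are linear", {
  set.seed(32)
  g <- tiny_panel(matrix(sample(0:2, 9, replace = TRUE), 3, 3))
  w <- c(0.5, -1.2, 2)
  mod <- prs_model(data.frame(id = colnames(g$dosages),
                              effect_allele = "A", other_allele = "G",
                              effect_weight = w))
  s <- compute_scores(harmonize_variants(mod, g), g)
  brute <- numeric(3)
  for (i in 1:3) for (j in 1:3) brute[i] <- brute[i] + w[j] * g$dosages[i, j]
  expect_equal(s$raw_score, brute)
  # null model gives all-zero scores
  mod0 <- prs_model(data.frame(id = colnames(g$dosages),
                               effect_allele = "A", other_allele = "G",
                               effect_weight = 0))
  expect_equal(compute_scores(harmonize_variants(mod0, g), g)$raw_score,
               rep(0, 3))
  # single variant linearity
  g1 <- tiny_panel(matrix(c(0, 1, 2), 3, 1))
  mod1 <- prs_model(data.frame(id = "rs001", effect_allele = "A",
                               other_allele = "G", effect_weight = 0.5))
  expect_equal(compute_scores(harmonize_variants(mod1, g1), g1)$raw_score,
               c(0, 0.5, 1.0))
})

test_that("scoring is invariant to sample order, variant order and global flips", {
  set.seed(33)
  n <- 30; L <- 8
  g <- tiny_panel(matrix(rbinom(n * L, 2, 0.4), n, L),
                  effect = rep("A", L), other = rep("G", L))
  w <- rnorm(L)
  mod <- prs_model(data.frame(id = colnames(g$dosages),
                              effect_allele = "A", other_allele = "G",
                              effect_weight = w))
  base <- compute_scores(harmonize_variants(mod, g), g)
  # permute samples
  perm <- sample(n)
  gp <- genotype_matrix(g$dosages[perm, ], g$variants)
  sp <- compute_scores(harmonize_variants(mod, gp), gp)
  expect_equal(sp$raw_score[match(base$sample_id, sp$sample_id)],
               base$raw_score)
  # permute model variant order
  mod2 <- prs_model(mod$variants[sample(L), c("id", "chr", "pos",
                                              "effect_allele",
                                              "other_allele",
                                              "effect_weight")])
  expect_equal(compute_scores(harmonize_variants(mod2, g), g)$raw_score,
               base$raw_score)
  # flip every panel variant's labels and dosages: scores unchanged
  vf <- g$variants
  tmp <- vf$effect_allele; vf$effect_allele <- vf$other_allele
  vf$other_allele <- tmp; vf$freq <- 1 - vf$freq
  gf <- genotype_matrix(2 - g$dosages, vf)
  sf <- compute_scores(harmonize_variants(mod, gf), gf)
  expect_equal(sf$raw_score, base$raw_score)
})

test_that("missing dosages are imputed by panel frequency or column mean", {
  d <- matrix(c(0, 1, 2, NA, 1, 1), 3, 2,
              dimnames = list(paste0("s", 1:3), c("rs001", "rs002")))
  g <- tiny_panel(d, freq = c(0.5, 0.25))
  mod <- prs_model(data.frame(id = c("rs001", "rs002"),
                              effect_allele = "A", other_allele = "G",
                              effect_weight = c(1, 1)))
  h <- harmonize_variants(mod, g)
  s_freq <- compute_scores(h, g, missing_policy = "freq")
  expect_equal(s_freq$raw_score[1], 0 + 2 * 0.25)  # imputed to 2f
  expect_equal(s_freq$n_variants_used, c(1L, 2L, 2L))
  s_mean <- compute_scores(h, g, missing_policy = "mean")
  expect_equal(s_mean$raw_score[1], 0 + 1)         # observed mean dosage
  expect_error(compute_scores(harmonize_variants(
    prs_model(mod$variants[0, ]), g), g), "zero harmonized")
})

test_that("standardization and its degenerate cases behave", {
  g <- tiny_panel(matrix(c(0, 1, 2), 3, 1))
  mod <- prs_model(data.frame(id = "rs001", effect_allele = "A",
                              other_allele = "G", effect_weight = 1))
  s <- compute_scores(harmonize_variants(mod, g), g)
  s_all <- standardize_scores(s)
  expect_equal(mean(s_all$std_score), 0)
  expect_equal(sd(s_all$std_score), 1)
  expect_equal(s_all$std_score, c(-1, 0, 1))
  # constant raw scores cannot be standardized
  mod0 <- prs_model(data.frame(id = "rs001", effect_allele = "A",
                               other_allele = "G", effect_weight = 0))
  s0 <- compute_scores(harmonize_variants(mod0, g), g)
  expect_error(standardize_scores(s0), "zero reference")
})

test_that("calibration turns SD units into centimeters sensibly", {
  sim <- small_sim()
  co <- sim$cohort
  fake_scores <- data.frame(sample_id = co$child_id,
                            raw_score = co$true_genetic_value_cm,
                            std_score = NA_real_, n_variants_used = 1L)
  class(fake_scores) <- c("score_vector", "data.frame")
  fake_scores <- standardize_scores(fake_scores)
  train <- seq_len(250)
  cal <- calibrate_to_cm(fake_scores, co$adult_height_cm, co$sex,
                         training = co$child_id[train])
  pred <- predict(cal, fake_scores$std_score, co$sex)
  test <- setdiff(seq_len(nrow(co)), train)
  r2 <- by(data.frame(o = co$adult_height_cm, p = pred, s = co$sex)[test, ],
           co$sex[test], function(d) cor(d$o, d$p)^2)
  # oracle genetic score: within-sex R2 near h2 = 0.8
  expect_equal(unname(r2[["female"]]), 0.8, tolerance = 0.08)
  expect_equal(unname(r2[["male"]]), 0.8, tolerance = 0.08)
  # doubling the raw scale before standardization leaves predictions alone
  doubled <- fake_scores
  doubled$raw_score <- doubled$raw_score * 2
  doubled <- standardize_scores(doubled)
  cal2 <- calibrate_to_cm(doubled, co$adult_height_cm, co$sex,
                          training = co$child_id[train])
  expect_equal(predict(cal2, doubled$std_score, co$sex), pred,
               tolerance = 1e-8)
  # a score uncorrelated with height has slope near zero
  set.seed(34)
  noise <- fake_scores
  noise$raw_score <- rnorm(nrow(co))
  noise <- standardize_scores(noise)
  cal0 <- calibrate_to_cm(noise, co$adult_height_cm, co$sex)
  expect_lt(abs(cal0$slope), 0.6)
  expect_equal(unname(cal0$intercepts["female"]),
               mean(co$adult_height_cm[co$sex == "female"]),
               tolerance = 1)
})
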