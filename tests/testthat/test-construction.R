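# Score construction: marginal scan, IVW meta-analysis, LD clumping,
# LASSO coordinate descent, model selection.

test_that("marginal scan is calibrated under the null", {
  set.seed(20)
  n <- 400; L <- 1000
  g <- tiny_panel(matrix(rbinom(n * L, 2, 0.4), n, L))
  y <- rnorm(n)  # independent of genotype
  sex <- rep(c("female", "male"), n / 2)
  ss <- marginal_gwas(g, y, data.frame(sex = sex))
  ks <- stats::ks.test(ss$p, "punif")
  expect_gt(ks$p.value, 0.001)
  expect_lt(abs(mean(ss$p < 0.05) - 0.05), 0.02)
})

test_that("marginal scan recovers a planted effect and matches lm", {
  set.seed(21)
  n <- 2000
  g <- tiny_panel(matrix(rbinom(n * 20, 2, 0.3), n, 20))
  sex <- sample(c("female", "male"), n, replace = TRUE)
  y <- 2 * g$dosages[, 7] + 5 * (sex == "male") + rnorm(n, 0, 4)
  ss <- marginal_gwas(g, y, data.frame(sex = sex))
  expect_lt(abs(ss$beta[7] - 2), 1.96 * ss$se[7])
  # exact agreement with the full per-variant lm fit
  ref <- summary(lm(y ~ g$dosages[, 7] + sex))$coefficients[2, ]
  expect_equal(ss$beta[7], unname(ref[1]), tolerance = 1e-10)
  expect_equal(ss$se[7], unname(ref[2]), tolerance = 1e-10)
  expect_equal(ss$p[7], unname(ref[4]), tolerance = 1e-10)
})

test_that("constant-dosage variants are flagged with the p = 1 convention", {
  set.seed(22)
  d <- matrix(rbinom(50 * 3, 2, 0.5), 50, 3)
  d[, 2] <- 2
  g <- tiny_panel(d)
  expect_message(ss <- marginal_gwas(g, rnorm(50)), "constant")
  expect_true(ss$constant[2])
  expect_true(is.na(ss$beta[2]))
  expect_equal(ss$p[2], 1)
})

test_that("inverse-variance meta-analysis matches hand arithmetic", {
  a <- data.frame(id = "rs1", chr = "1", pos = 1, effect_allele = "A",
                  other_allele = "G", beta = 1, se = 1, p = 0.3,
                  eaf = 0.4, n = 100, stringsAsFactors = FALSE)
  b <- a; b$beta <- 3
  m <- ivw_meta_analysis(a, b)
  expect_equal(m$beta, 2.0)
  expect_equal(m$se, 1 / sqrt(2), tolerance = 1e-12)
  # equal duplicate studies: beta unchanged, se / sqrt(2)
  m2 <- ivw_meta_analysis(a, a)
  expect_equal(m2$beta, a$beta)
  expect_equal(m2$se, a$se / sqrt(2))
  # allele-swapped record flips sign before combining
  bs <- a
  bs$effect_allele <- "G"; bs$other_allele <- "A"; bs$beta <- -1
  bs$eaf <- 0.6
  m3 <- ivw_meta_analysis(a, bs)
  expect_equal(m3$beta, 1.0)
  expect_equal(m3$eaf, 0.4)
  # single-input variants pass through bit-identically
  solo <- a; solo$id <- "rs_only_a"
  m4 <- ivw_meta_analysis(rbind(a, solo), b)
  passthrough <- m4[m4$id == "rs_only_a", ]
  rownames(passthrough) <- rownames(solo) <- NULL
  expect_identical(passthrough, solo)
  # irreconcilable alleles dropped with a message
  bad <- a; bad$effect_allele <- "T"; bad$other_allele <- "C"
  expect_message(m5 <- ivw_meta_analysis(a, bad), "irreconcilable")
  expect_equal(nrow(m5), 0)
})

test_that("clumping keeps one of a duplicated column and is idempotent", {
  set.seed(23)
  n <- 300
  d <- matrix(rbinom(n * 6, 2, 0.5), n, 6)
  d[, 4] <- d[, 2]  # perfect LD pair
  g <- tiny_panel(d)
  y <- d[, 2] * 0.8 + rnorm(n)
  ss <- marginal_gwas(g, y)
  prm <- clump_params(r2_threshold = 0.1, window = 10, p_thresholds = 1)
  kept <- ld_clump_threshold(ss, g, prm)[[1]]
  pair <- intersect(kept$id, c("rs002", "rs004"))
  expect_length(pair, 1)
  expect_equal(pair, ss$id[which.min(ss$p[c(2, 4)]) * 2])
  # idempotence: clumping the clumped set changes nothing
  ss2 <- ss[ss$id %in% kept$id, ]
  g2 <- tiny_panel(g$dosages[, match(ss2$id, colnames(g$dosages)),
                             drop = FALSE])
  kept2 <- ld_clump_threshold(ss2, g2, prm)[[1]]
  expect_setequal(kept2$id, kept$id)
})

test_that("uncorrelated variants all survive and p filters nest", {
  set.seed(24)
  n <- 500
  g <- tiny_panel(matrix(rbinom(n * 8, 2, 0.5), n, 8))
  y <- rnorm(n)
  ss <- marginal_gwas(g, y)
  prm <- clump_params(r2_threshold = 0.05, window = 10,
                      p_thresholds = c(0.2, 1))
  sets <- ld_clump_threshold(ss, g, prm)
  expect_equal(nrow(sets[[2]]), 8)             # vacuous p filter
  expect_true(all(sets[[1]]$id %in% sets[[2]]$id))
  expect_true(all(sets[[1]]$p <= 0.2))
})

test_that("ties in clumping break by variant id", {
  d <- cbind(c(0, 1, 2, 1), c(0, 2, 0, 2))  # uncorrelated pair
  d <- cbind(d, d[, 1])  # rs003 duplicates rs001
  g <- tiny_panel(d)
  ss <- data.frame(id = c("rs001", "rs002", "rs003"), chr = "1",
                   pos = 1:3, effect_allele = "A", other_allele = "G",
                   beta = 1, se = 1, p = c(0.5, 0.1, 0.5), eaf = 0.5,
                   n = 4, stringsAsFactors = FALSE)
  kept <- ld_clump_threshold(ss, g, clump_params(0.1, 10, 1))[[1]]
  expect_true("rs001" %in% kept$id)   # equal p: lexicographic winner
  expect_false("rs003" %in% kept$id)
})

test_that("lasso shrinks fully at lambda_max and matches OLS at zero", {
  set.seed(25)
  n <- 200
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("v", 1:5)))
  sex <- rep(c("female", "male"), n / 2)
  y <- as.numeric(X %*% c(1, -2, 0, 0.5, 0) + 3 * (sex == "male") + rnorm(n))
  # lambda at/above max |X'r|/n zeroes every penalized coefficient
  p0 <- lasso_fit_path(X, y, data.frame(sex = sex), lambda_grid = 10)
  expect_true(all(p0$beta == 0))
  # lambda = 0 reproduces the normal-equation solution
  p1 <- lasso_fit_path(X, y, data.frame(sex = sex),
                       lambda_grid = c(0.5, 0.05, 0))
  ols <- coef(lm(y ~ X + sex))[2:6]
  expect_lt(max(abs(p1$beta[, 3] - ols)), 1e-4)
  # nonzero count non-increasing in lambda along the path
  expect_true(all(diff(p1$df) >= 0))
  expect_error(lasso_fit_path(X, y, NULL, lambda_grid = c(0.1, 0.5)),
               "descending")
})

test_that("lasso equals the soft-threshold closed form when orthonormal", {
  set.seed(26)
  n <- 100
  M <- qr.Q(qr(cbind(1, matrix(rnorm(n * 4), n, 4))))[, 2:5] * sqrt(n)
  colnames(M) <- paste0("q", 1:4)
  y <- as.numeric(M %*% c(2, -1, 0.3, 0) + rnorm(n) * 0.1)
  bols <- as.numeric(crossprod(M, y - mean(y)) / n)
  for (lam in c(0.2, 0.8)) {
    fit <- lasso_fit_path(M, y, NULL, lambda_grid = lam)
    expect_equal(unname(fit$beta[, 1]),
                 sign(bols) * pmax(abs(bols) - lam, 0), tolerance = 1e-8)
  }
})

test_that("lasso agrees with glmnet on a shared grid", {
  skip_if_not_installed("glmnet")
  set.seed(27)
  n <- 300
  X <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("v", 1:10)))
  y <- as.numeric(X[, 1] - 0.5 * X[, 4] + rnorm(n))
  lam <- c(0.3, 0.1, 0.02)
  mine <- lasso_fit_path(X, y, NULL, lambda_grid = lam)
  gn <- glmnet::glmnet(X, y, lambda = lam, standardize = TRUE,
                       thresh = 1e-12)
  expect_equal(unname(mine$beta), unname(as.matrix(gn$beta)),
               tolerance = 1e-3)
})

test_that("model selection maximizes adjusted R2 with declared tie-breaks", {
  sim <- small_sim()
  co <- sim$cohort
  child_g <- genotype_matrix(sim$genotypes$dosages[co$child_id, ],
                             sim$genotypes$variants)
  v <- sim$genotypes$variants
  oracle <- data.frame(id = v$id, effect_allele = v$effect_allele,
                       other_allele = v$other_allele,
                       weight = sim$effects, stringsAsFactors = FALSE)
  oracle <- oracle[oracle$weight != 0, ]
  set.seed(28)
  noise <- oracle
  noise$weight <- sample(noise$weight)
  sel <- select_model(list(oracle = oracle, noise = noise), child_g,
                      co$adult_height_cm, co$sex)
  expect_equal(sel$name, "oracle")
  # single candidate passes through
  one <- select_model(list(only = oracle), child_g,
                      co$adult_height_cm, co$sex)
  expect_equal(one$name, "only")
  expect_equal(one$model$variants$effect_weight, oracle$weight)
  # identical candidates: equal fit and size, first listed wins
  sel2 <- select_model(list(b_dup = oracle, a_dup = oracle), child_g,
                       co$adult_height_cm, co$sex)
  expect_equal(sel2$name, "b_dup")  # equal fit, equal size: first listed
  expect_error(select_model(list(), child_g, co$adult_height_cm, co$sex),
               "empty")
})

test_that("causal variants are enriched in a desk-scale construction", {
  p <- sim_params(n_families = 1200, n_loci = 300, n_causal = 30,
                  h2 = 0.6, seed = 29)
  sim <- simulate_trio_cohort(p)
  co <- sim$cohort
  fg <- genotype_matrix(
    sim$genotypes$dosages[c(co$mother_id, co$father_id), ],
    sim$genotypes$variants)
  built <- construct_prs(
    fg, c(co$mother_height_cm, co$father_height_cm),
    rep(c("female", "male"), each = nrow(co)),
    split_fractions = c(train = 0.6, selection = 0.15, test = 0.25),
    clump = clump_params(r2_threshold = 0.1, window = 50,
                         p_thresholds = c(1e-4, 1e-2, 0.1)),
    lasso_max_variants = 120, n_lambda = 12, seed = 30)
  causal_ids <- sim$genotypes$variants$id[sim$effects != 0]
  sel_ids <- built$model$variants$id
  enrich <- mean(sel_ids %in% causal_ids) /
    (length(causal_ids) / p$n_loci)
  expect_gt(enrich, 5)
})
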