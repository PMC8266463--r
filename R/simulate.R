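#' Simulation parameters for a trio cohort
#'
#' Bundles and validates every knob of the generative model: diploid
#' biallelic genotypes in Hardy-Weinberg founders, phenotypic assortative
#' mate pairing, Mendelian transmission to one child per family, and adult
#' height decomposed as sex effect + additive genetic value + shared family
#' environment + unique environment. Defaults target the variance structure
#' of a large adult European-ancestry cohort: within-sex SDs of 6.2 cm
#' (female) and 6.8 cm (male), narrow-sense heritability 0.8, no shared
#' environment and random mating.
#'
#' @param n_families Number of families (one child each).
#' @param n_loci Number of unlinked biallelic loci.
#' @param n_causal Number of loci with nonzero effect; defaults to all loci
#'   (fully polygenic trait).
#' @param allele_freq_range Range from which per-locus effect-allele
#'   frequencies are drawn uniformly; both ends strictly inside (0, 1).
#' @param h2 Narrow-sense heritability of height within sex, in \[0, 1\].
#' @param c2 Shared-family-environment variance fraction, in \[0, 1);
#'   a single normal deviate per family added to mother, father and child.
#' @param rho_am Target spousal phenotypic correlation in \[0, 1);
#'   realized by Gaussian-copula rank matching.
#' @param sex_means Named numeric, mean adult height in cm for
#'   `female` and `male`.
#' @param sex_sds Named numeric, within-sex phenotypic SD in cm.
#' @param growth_ages Half-year age grid in \[8, 17\] for childhood records.
#' @param growth_noise_sd Measurement noise SD (cm) on childhood heights,
#'   emulating self-reported measurements.
#' @param seed Integer seed; identical parameters give bit-identical cohorts.
#'
#' @return An object of class `sim_params` (a validated list).
#' @export
sim_params <- function(n_families = 5000,
                       n_loci = 1000,
                       n_causal = n_loci,
                       allele_freq_range = c(0.05, 0.95),
                       h2 = 0.8,
                       c2 = 0,
                       rho_am = 0,
                       sex_means = c(female = 162.6, male = 175.8),
                       sex_sds = c(female = 6.2, male = 6.8),
                       growth_ages = seq(8, 17, by = 0.5),
                       growth_noise_sd = 1.5,
                       seed = 1L) {
  .assert(.is_count(n_families), "n_families must be a positive integer")
  .assert(.is_count(n_loci), "n_loci must be a positive integer")
  .assert(.is_count(n_causal) && n_causal <= n_loci,
          "n_causal must be a positive integer <= n_loci")
  .assert(length(allele_freq_range) == 2L &&
            all(is.finite(allele_freq_range)) &&
            all(allele_freq_range > 0) && all(allele_freq_range < 1) &&
            allele_freq_range[1] <= allele_freq_range[2],
          "allele_freq_range must be two frequencies strictly inside (0, 1)")
  .assert(.is_prob(h2), "h2 must be in [0, 1]")
  .assert(.is_prob(c2, open_right = TRUE), "c2 must be in [0, 1)")
  .assert(h2 + c2 <= 1, "h2 + c2 must not exceed 1")
  .assert(.is_prob(rho_am, open_right = TRUE), "rho_am must be in [0, 1)")
  for (nm in c("female", "male")) {
    .assert(is.finite(sex_means[[nm]]) && sex_means[[nm]] > 0,
            paste0("sex_means['", nm, "'] must be positive"))
    .assert(is.finite(sex_sds[[nm]]) && sex_sds[[nm]] > 0,
            paste0("sex_sds['", nm, "'] must be positive"))
  }
  .assert(all(growth_ages >= 8 & growth_ages <= 17),
          "growth_ages must lie in [8, 17]")
  .assert(all(abs(growth_ages * 2 - round(growth_ages * 2)) < 1e-8),
          "growth_ages must sit on the half-year grid")
  .assert(is.finite(growth_noise_sd) && growth_noise_sd >= 0,
          "growth_noise_sd must be non-negative")
  .assert(.is_count(seed) || (is.numeric(seed) && seed == floor(seed)),
          "seed must be an integer")
  structure(list(
    n_families = as.integer(n_families),
    n_loci = as.integer(n_loci),
    n_causal = as.integer(n_causal),
    allele_freq_range = as.numeric(allele_freq_range),
    h2 = h2, c2 = c2, rho_am = rho_am,
    sex_means = sex_means[c("female", "male")],
    sex_sds = sex_sds[c("female", "male")],
    growth_ages = as.numeric(growth_ages),
    growth_noise_sd = growth_noise_sd,
    seed = as.integer(seed)
  ), class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Trio simulation parameters\n")
  cat(sprintf("  families: %d, loci: %d (%d causal)\n",
              x$n_families, x$n_loci, x$n_causal))
  cat(sprintf("  h2 = %.2f, c2 = %.2f, spousal correlation = %.2f\n",
              x$h2, x$c2, x$rho_am))
  cat(sprintf("  female %0.1f (%.1f) cm, male %0.1f (%.1f) cm\n",
              x$sex_means[["female"]], x$sex_sds[["female"]],
              x$sex_means[["male"]], x$sex_sds[["male"]]))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Genotype container

#' Construct a genotype matrix object
#'
#' A thin container pairing an integer dosage matrix (samples x variants,
#' effect-allele counts in \{0, 1, 2\} or NA) with a variant table carrying
#' chromosome, position, allele labels and the effect-allele frequency used
#' to generate (or estimated from) the dosages.
#'
#' @param dosages Numeric matrix, rows = samples, columns = variants;
#'   rownames/colnames are sample/variant ids.
#' @param variants data.frame with columns `id`, `chr`, `pos`,
#'   `effect_allele`, `other_allele`, `freq`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, variants) {
  .assert(is.matrix(dosages), "dosages must be a matrix")
  .assert(!is.null(rownames(dosages)) && !anyDuplicated(rownames(dosages)),
          "sample ids (rownames) must be present and unique")
  .assert(!is.null(colnames(dosages)) && !anyDuplicated(colnames(dosages)),
          "variant ids (colnames) must be present and unique")
  .assert(all(colnames(dosages) == variants$id),
          "variant table must match dosage columns in order")
  ok <- dosages %in% c(0, 1, 2) | is.na(dosages)
  .assert(all(ok), "dosages must be 0, 1, 2 or NA")
  structure(list(dosages = dosages, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (%.2f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

.make_variant_table <- function(n_loci, freqs) {
  bases <- c("A", "C", "G", "T")
  ea <- sample(bases, n_loci, replace = TRUE)
  oa <- vapply(ea, function(b) sample(setdiff(bases, b), 1L), character(1))
  data.frame(
    id = sprintf("rs%06d", seq_len(n_loci)),
    chr = as.character(rep_len(1:22, n_loci)),
    pos = seq_len(n_loci) * 5000L,
    effect_allele = ea,
    other_allele = unname(oa),
    freq = freqs,
    stringsAsFactors = FALSE
  )
}

#' Draw founder genotypes under Hardy-Weinberg equilibrium
#'
#' Generates `2 * n_families` founders (mothers then fathers). Per locus the
#' effect-allele frequency is drawn uniformly from `allele_freq_range` and
#' dosages are independent Binomial(2, f) across loci and individuals.
#'
#' @param params A [sim_params()] object; its `seed` fully determines the
#'   output.
#' @return A [genotype_matrix()] with sample ids `M0001..` (mothers) and
#'   `F0001..` (fathers).
#' @export
draw_founder_genotypes <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  n <- 2L * params$n_families
  L <- params$n_loci
  freqs <- stats::runif(L, params$allele_freq_range[1],
                        params$allele_freq_range[2])
  variants <- .make_variant_table(L, freqs)
  d <- matrix(stats::rbinom(n * L, 2L, rep(freqs, each = n)),
              nrow = n, ncol = L)
  rownames(d) <- c(sprintf("M%05d", seq_len(params$n_families)),
                   sprintf("F%05d", seq_len(params$n_families)))
  colnames(d) <- variants$id
  genotype_matrix(d, variants)
}

#' Pair mothers and fathers with a target spousal correlation
#'
#' Gaussian-copula rank matching: mothers' phenotypes are converted to
#' normal scores, a latent normal with correlation `rho_am` is drawn, and
#' fathers are assigned by matching the ranks of their phenotypes to the
#' ranks of the latent variable. `rho_am = 0` reduces to random pairing.
#'
#' @param mother_phenotype,father_phenotype Numeric vectors of equal length.
#' @param rho_am Target spousal phenotypic correlation in \[0, 1).
#' @param seed Optional integer seed; NULL uses the current RNG stream.
#' @return Integer vector `idx` such that mother `i` is paired with father
#'   `idx[i]`.
#' @export
pair_mates_assortatively <- function(mother_phenotype, father_phenotype,
                                     rho_am, seed = NULL) {
  .assert(length(mother_phenotype) == length(father_phenotype),
          "equal numbers of mothers and fathers required")
  .assert(.is_prob(rho_am, open_right = TRUE), "rho_am must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  n <- length(mother_phenotype)
  if (rho_am == 0) return(sample.int(n))
  # Normal scores of maternal phenotype; latent target correlated rho_am.
  zm <- stats::qnorm((rank(mother_phenotype, ties.method = "random")) /
                       (n + 1))
  latent <- rho_am * zm + sqrt(1 - rho_am^2) * stats::rnorm(n)
  # Father with k-th smallest phenotype goes to the mother whose latent
  # value has rank k.
  father_order <- order(father_phenotype)
  idx <- integer(n)
  idx[order(latent)] <- father_order
  idx
}

#' Transmit alleles from parents to children (unlinked loci)
#'
#' Per locus each child receives one allele from each parent, drawn
#' uniformly from that parent's two alleles; loci are independent
#' (no linkage). A missing parental dosage makes the child's locus missing.
#'
#' @param mother_dosages,father_dosages Numeric matrices
#'   (children x loci) of the paired parents' dosages in \{0, 1, 2\}.
#' @param seed Optional integer seed.
#' @return Matrix of child dosages with the dimensions of the inputs.
#' @export
meiosis_transmit <- function(mother_dosages, father_dosages, seed = NULL) {
  .assert(all(dim(mother_dosages) == dim(father_dosages)),
          "parental dosage matrices must have identical dimensions")
  ok <- function(m) all(m %in% c(0, 1, 2) | is.na(m))
  .assert(ok(mother_dosages) && ok(father_dosages),
          "parental dosages must be 0, 1, 2 or NA")
  if (!is.null(seed)) set.seed(seed)
  draw <- function(d) {
    a <- matrix(stats::rbinom(length(d), 1L, ifelse(is.na(d), 0, d / 2)),
                nrow = nrow(d))
    a[is.na(d)] <- NA_integer_
    a
  }
  child <- draw(mother_dosages) + draw(father_dosages)
  dimnames(child) <- dimnames(mother_dosages)
  child
}

# Standardized additive genetic value: dosages weighted by per-locus
# effects, centered and scaled by the theoretical HWE moments so that
# founders and children share one scale.
.genetic_score_std <- function(dosages, weights, freqs) {
  mu <- sum(2 * freqs * weights)
  v <- sum(weights^2 * 2 * freqs * (1 - freqs))
  .assert(v > 0, "at least one causal locus with nonzero frequency needed")
  as.numeric(dosages %*% weights - mu) / sqrt(v)
}

#' Assign adult heights from genotypes and variance components
#'
#' Height = sex mean + sex SD * (sqrt(h2) g + sqrt(c2) f + sqrt(1 - h2 - c2) e)
#' where `g` is the standardized additive genetic value, `f` a family-level
#' shared-environment deviate and `e` unique environment. By construction the
#' within-sex phenotypic variance is the configured sex SD squared and the
#' within-sex genetic variance fraction is `h2`.
#'
#' @param genotypes A [genotype_matrix()].
#' @param effects Per-variant effect weights (length = number of variants).
#' @param sex Sex of each sample (female/male codes accepted).
#' @param params A [sim_params()] object (supplies h2, c2, sex moments).
#' @param shared_env Optional per-sample standard-normal family deviate;
#'   0 when `c2 = 0` and NULL.
#' @param seed Optional integer seed for the unique-environment draw.
#' @return data.frame with `height_cm` and `genetic_value_cm`
#'   (= sex SD * sqrt(h2) * g, the oracle genetic score).
#' @export
assign_phenotypes <- function(genotypes, effects, sex, params,
                              shared_env = NULL, seed = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(params, "sim_params"))
  .assert(params$h2 + params$c2 <= 1, "h2 + c2 must not exceed 1")
  if (!is.null(seed)) set.seed(seed)
  sex <- .norm_sex(sex)
  n <- nrow(genotypes$dosages)
  .assert(length(sex) == n, "sex must have one entry per sample")
  if (is.null(shared_env)) shared_env <- numeric(n)
  g <- .genetic_score_std(genotypes$dosages, effects, genotypes$variants$freq)
  e <- stats::rnorm(n)
  z <- sqrt(params$h2) * g + sqrt(params$c2) * shared_env +
    sqrt(1 - params$h2 - params$c2) * e
  sd_s <- params$sex_sds[as.character(sex)]
  mu_s <- params$sex_means[as.character(sex)]
  data.frame(
    height_cm = as.numeric(mu_s + sd_s * z),
    genetic_value_cm = as.numeric(sd_s * sqrt(params$h2) * g)
  )
}

#' Simulate a complete trio cohort
#'
#' End-to-end generator: Hardy-Weinberg founders, effect weights drawn once
#' (normal at causal loci, zero elsewhere), assortative pairing on the
#' pre-family-environment phenotype, one child per family by Mendelian
#' transmission, and phenotypes for all 3 * n_families individuals. The
#' shared family environment is a single normal deviate per family common to
#' mother, father and child.
#'
#' @param params A [sim_params()] object.
#' @param keep_parent_genotypes Keep founder genotype rows in the output
#'   (needed for score construction); children's rows are always kept.
#' @param growth Also generate childhood growth records
#'   (see [generate_growth_records()]).
#' @return An object of class `trio_cohort`: list with `cohort` (one row per
#'   family), `genotypes` (a [genotype_matrix()]), `effects` (true
#'   per-variant weights on the standardized-genetic-value scale), `growth`
#'   (NULL or a data.frame) and `params`.
#' @export
simulate_trio_cohort <- function(params = sim_params(),
                                 keep_parent_genotypes = TRUE,
                                 growth = FALSE) {
  stopifnot(inherits(params, "sim_params"))
  founders <- draw_founder_genotypes(params)  # seeds the RNG stream
  nfam <- params$n_families
  L <- params$n_loci

  causal <- sort(sample.int(L, params$n_causal))
  effects <- numeric(L)
  effects[causal] <- stats::rnorm(params$n_causal)

  freqs <- founders$variants$freq
  g_founder <- .genetic_score_std(founders$dosages, effects, freqs)
  e_founder <- stats::rnorm(2L * nfam)
  # Pairing happens on the phenotype before the family component exists:
  # spouses share an environment only once they are a family.
  z_pre <- sqrt(params$h2) * g_founder +
    sqrt(1 - params$h2 - params$c2) * e_founder
  sex_founder <- rep(c("female", "male"), each = nfam)
  sd_f <- params$sex_sds[sex_founder]
  mu_f <- params$sex_means[sex_founder]
  height_pre <- mu_f + sd_f * z_pre

  midx <- seq_len(nfam)
  fidx <- nfam + pair_mates_assortatively(height_pre[midx],
                                          height_pre[nfam + midx],
                                          params$rho_am)

  fam_env <- stats::rnorm(nfam)
  height_founder <- height_pre
  height_founder[midx] <- height_founder[midx] +
    sd_f[midx] * sqrt(params$c2) * fam_env
  height_founder[fidx] <- height_founder[fidx] +
    sd_f[fidx] * sqrt(params$c2) * fam_env

  child_d <- meiosis_transmit(founders$dosages[midx, , drop = FALSE],
                              founders$dosages[fidx, , drop = FALSE])
  child_ids <- sprintf("C%05d", seq_len(nfam))
  rownames(child_d) <- child_ids
  child_sex <- sample(c("female", "male"), nfam, replace = TRUE)
  g_child <- .genetic_score_std(child_d, effects, freqs)
  e_child <- stats::rnorm(nfam)
  z_child <- sqrt(params$h2) * g_child + sqrt(params$c2) * fam_env +
    sqrt(1 - params$h2 - params$c2) * e_child
  sd_c <- params$sex_sds[child_sex]
  height_child <- params$sex_means[child_sex] + sd_c * z_child

  cohort <- data.frame(
    family_id = sprintf("FAM%05d", seq_len(nfam)),
    child_id = child_ids,
    mother_id = rownames(founders$dosages)[midx],
    father_id = rownames(founders$dosages)[fidx],
    sex = .norm_sex(child_sex),
    adult_height_cm = as.numeric(height_child),
    mother_height_cm = as.numeric(height_founder[midx]),
    father_height_cm = as.numeric(height_founder[fidx]),
    true_genetic_value_cm = as.numeric(sd_c * sqrt(params$h2) * g_child),
    stringsAsFactors = FALSE
  )

  if (keep_parent_genotypes) {
    d <- rbind(child_d, founders$dosages)
  } else {
    d <- child_d
  }
  genotypes <- genotype_matrix(d, founders$variants)

  out <- structure(list(cohort = cohort, genotypes = genotypes,
                        effects = effects, growth = NULL, params = params),
                   class = "trio_cohort")
  if (growth) out <- generate_growth_records(out)
  out
}

#' @export
print.trio_cohort <- function(x, ...) {
  cat(sprintf("trio_cohort: %d families, %d loci\n",
              nrow(x$cohort), ncol(x$genotypes$dosages)))
  cat(sprintf("  genotyped samples: %d; growth records: %s\n",
              nrow(x$genotypes$dosages),
              if (is.null(x$growth)) "none" else
                format(nrow(x$growth), big.mark = ",")))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Childhood growth records

# Reference completion fractions (childhood height / adult height) at whole
# ages, per sex; girls complete growth earlier than boys. Piecewise-linear
# in age on the half-year grid.
.growth_frac_table <- list(
  female = data.frame(
    age = 8:17,
    frac = c(0.783, 0.817, 0.848, 0.886, 0.927, 0.961, 0.981, 0.990,
             0.995, 0.998)),
  male = data.frame(
    age = 8:17,
    frac = c(0.724, 0.756, 0.785, 0.813, 0.845, 0.885, 0.927, 0.962,
             0.983, 0.993))
)

.growth_fraction <- function(sex, age) {
  sex <- as.character(.norm_sex(sex))
  out <- numeric(length(age))
  for (s in unique(sex)) {
    tab <- .growth_frac_table[[s]]
    sel <- sex == s
    out[sel] <- stats::approx(tab$age, tab$frac, xout = age[sel],
                              rule = 2)$y
  }
  out
}

# Reference BMI trajectory used for the weight model (kg/m^2 at age a).
.ref_bmi <- function(age) 16 + 0.55 * (age - 8)

#' Generate childhood growth records
#'
#' Childhood height at age `a` is the adult height scaled by a sex-specific
#' monotone completion fraction (piecewise-linear between whole ages, with
#' >= 99% of adult height reached by age 17) plus measurement noise. Weight
#' follows a reference BMI trajectory applied to the noiseless height, plus
#' noise.
#'
#' @param sim A `trio_cohort` from [simulate_trio_cohort()].
#' @param ages Half-year ages in \[8, 17\]; defaults to `params$growth_ages`.
#' @param seed Optional integer seed.
#' @return The `trio_cohort` with a `growth` data.frame
#'   (`child_id`, `age_years`, `height_cm`, `weight_kg`).
#' @export
generate_growth_records <- function(sim, ages = NULL, seed = NULL) {
  stopifnot(inherits(sim, "trio_cohort"))
  params <- sim$params
  if (is.null(ages)) ages <- params$growth_ages
  .assert(all(ages >= 8 & ages <= 17), "growth ages must lie in [8, 17]")
  if (!is.null(seed)) set.seed(seed)
  co <- sim$cohort
  n <- nrow(co)
  recs <- vector("list", length(ages))
  for (k in seq_along(ages)) {
    a <- ages[k]
    frac <- .growth_fraction(co$sex, rep(a, n))
    h_true <- co$adult_height_cm * frac
    h <- h_true + stats::rnorm(n, 0, params$growth_noise_sd)
    w <- .ref_bmi(a) * (h_true / 100)^2 + stats::rnorm(n, 0, 1.5)
    recs[[k]] <- data.frame(child_id = co$child_id, age_years = a,
                            height_cm = h, weight_kg = pmax(w, 10),
                            stringsAsFactors = FALSE)
  }
  growth <- do.call(rbind, recs)
  growth <- growth[order(growth$child_id, growth$age_years), ]
  rownames(growth) <- NULL
  sim$growth <- growth
  sim
}
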