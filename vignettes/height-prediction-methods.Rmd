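---
title: "Methods: polygenic and parental prediction of adult stature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic and parental prediction of adult stature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# What the package computes

`statureprs` compares genetic and parental predictors of adult standing
height, and their ability to screen children for future adult short
stature. Its components are:

1. a **trio cohort simulator** generating genotypes and phenotypes with the
   statistical structure these comparisons assume;
2. a **desk-scale polygenic-score construction pipeline** (marginal
   association scan, fixed-effect inverse-variance meta-analysis, LD
   clumping with p-value thresholding, a LASSO arm, and candidate selection
   on a held-out split);
3. **scoring**: PGS-Catalog-style scoring files, allele harmonization
   against a genotype panel, standardized scores and calibration to
   centimeter-scale predicted heights;
4. the **height predictors** being compared: classical mid-parental height
   (parental mean ± 6.5 cm by child sex), the adapted sex-specific affine
   formulas (0.75·mean + 37.85 cm for girls, 0.78·mean + 45.99 cm for
   boys), single-parent and fitted combination predictors, and the
   Khamis-Roche age-specific predictor with a pluggable genetic component;
5. an **evaluation suite**: adjusted R², RMSE, the within-sex short-stature
   rule (mean − 2 SD, ≈ the shortest 2.3% under normality), Mann-Whitney
   AUROC, average-precision AUPRC, odds ratio per SD decrease, Gaussian-ML
   nested likelihood-ratio tests, and percentile bootstrap CIs.

# The generative model

Each family contributes a mother, a father and one child. For individual
$i$ of sex $s$,

$$ H_i = \mu_s + \sigma_s\left(\sqrt{h^2}\, g_i + \sqrt{c^2}\, f_{F(i)} +
\sqrt{1 - h^2 - c^2}\, e_i\right), $$

where $g_i$ is the standardized additive genetic value, $f_{F(i)}$ a
standard-normal deviate shared by everyone in family $F(i)$ (the
shared-environment component), and $e_i$ unique environment. Genotypes are
unlinked biallelic loci; founders are Binomial(2, $f_j$) under
Hardy-Weinberg with $f_j$ uniform on a configurable range, and children
receive one uniformly chosen allele per parent per locus. Effect weights
are drawn once (normal at causal loci) and $g$ is standardized by its
theoretical Hardy-Weinberg moments, so founders and children live on one
scale and the within-sex variance decomposition is exact by construction.

Defaults: 5000 families, 1000 loci (all causal), $h^2 = 0.8$ — the
commonly cited narrow-sense heritability of adult height — $c^2 = 0$,
random mating, female mean (SD) 162.6 (6.2) cm and male 175.8 (6.8) cm,
matching the adult moments of a large European-ancestry biobank training
cohort.

**Assortative mating** is phenotypic, by Gaussian-copula rank matching:
mothers' phenotypes are converted to normal scores, a latent normal with
correlation `rho_am` is drawn, and fathers are matched rank-to-rank to the
latent variable. Pairing happens *before* the family component is added —
spouses share an environment only once they are a family — so the realized
spousal correlation is approximately `rho_am (1 - c2) + c2`. The default is
`rho_am = 0`.

**Why these choices.** The comparisons the package makes are driven by
three resemblance parameters, all of which have closed forms under this
model (random mating, $c^2=0$, within sex):

* parent-offspring phenotypic correlation $h^2/2$;
* mid-parental height $R^2 = h^4/2$ (0.32 at $h^2 = 0.8$), single parent
  $h^4/4$ (0.16);
* a perfect genetic score $R^2 = h^2$ (0.80);
* child-on-midparent regression slope $h^2$ on sex-standardized heights.

These closed forms are the package's strongest correctness checks: the
simulator must reproduce them, and does, to Monte-Carlo accuracy, at
50 000 trios. With unequal sex SDs the *cm-scale* closed forms hold only
approximately (the within-sex R² forms are exact; the pooled slope is a
sex-SD-weighted blend), so the tests assert them within sex or on
sex-standardized values.

**Shared environment.** A single family-level normal component is the
minimal structure that makes mid-parental height capture non-genetic
variance: it raises the parent-child covariance by $c^2$ while leaving a
genetic score untouched. The package's property tests verify exactly this
asymmetry (raising $c^2$ from 0 to 0.15 raises MPH's within-sex $R^2$ by
the predicted ≈ 0.2 while the oracle score's $R^2$ stays within ±0.02).

**Growth records.** Childhood height at age $a$ is
`adult height × frac(sex, a) + noise`, with a monotone per-sex completion
fraction table (piecewise-linear between whole ages, girls completing
earlier than boys, ≥ 99% of adult height by age 17) and self-report noise
of SD 1.5 cm by default — a declared guess, since no measurement-error
magnitude is available for questionnaire heights. Weight follows a
reference BMI trajectory (16 kg/m² at age 8 rising to ≈ 21 at 17) applied
to the noiseless height. This generator has **no pubertal-timing
variation**: every child follows the same completion schedule up to
measurement noise. Consequently childhood height is a much cleaner proxy
of adult height than in real cohorts, and Khamis-Roche-style accuracy at
young ages is optimistic; age-profile *shapes* (accuracy non-decreasing in
age) are meaningful, absolute levels are not.

# Score construction at desk scale

The construction pipeline reproduces the *shape* of a biobank workflow on
founder genotypes: the training split is halved into two pseudo-studies
whose marginal scans (least-squares effect of dosage adjusting for sex,
exact per-variant `lm` via Frisch-Waugh residualization) are combined by
fixed-effect inverse-variance weighting — the standard for GWAS
meta-analysis, with sign flips for swapped-allele records; candidates come
from greedy LD clumping (ascending p, ties by variant id for deterministic
builds; a selected variant removes unselected variants with squared dosage
correlation above `r2_threshold` within a column window) crossed with a
p-threshold grid, and from a LASSO path. The winner maximizes adjusted R²
(with sex) on the model-selection split, ties going to fewer variants.
Split fractions default to ≈ 80 / 1.5 / 18.5 percent
(training / selection / test), the proportions of the study design this
mirrors.

The LASSO is cyclic coordinate descent with soft-thresholding on
internally standardized predictors, unpenalized covariates handled by
residualization (exact for unpenalized blocks), warm starts along a
descending grid, convergence when the largest coefficient change in a
sweep falls below 10⁻⁶, and a hard error naming the lambda after 10⁴
sweeps. It is verified against the normal-equation solution at λ = 0, the
soft-threshold closed form on orthonormal designs, and `glmnet` on a
shared grid. An LDpred-style Gibbs arm is deliberately absent: the
clump+threshold and LASSO arms span the candidate family at this scale.

# Scoring and calibration

Harmonization matches variants by id: exact allele matches are kept;
swapped effect/other alleles are kept with the dosage complemented
(d → 2 − d) at scoring time; anything else — absent variants, allele pairs
inconsistent with both orientations — is discarded and counted. The
accounting identity kept + flipped + discarded = model size is enforced by
a property test, as is invariance of scores under a global flip of the
panel's allele labels. Strand-ambiguous (A/T, C/G) variants are kept when
ids match — simulated data have no strand problem — with a
`drop_palindromic` flag for real data. Sporadically missing dosages are
imputed to 2 × (panel effect-allele frequency) by default, or the observed
mean dosage on request; whole-variant absence is always a discard.

Raw scores (Σ wᵢⱼ dᵢⱼ) are standardized against a declared reference group
— the package standardizes within the evaluation cohort of children, a
config choice since the original analysis does not state its reference —
and calibrated to centimeters by regressing height on the standardized
score with sex-specific intercepts on a split disjoint from evaluation
(the founder test split in the pipeline). Calibration-by-regression is the
minimal faithful reading of "genetically predicted height"; predictions
are invariant to any rescaling of the raw score.

# Evaluation conventions

* **Short stature**: height below (sex mean − 2 SD), moments from the
  evaluation cohort itself rather than an external growth reference; an
  empirical 2.3%-quantile mode is provided and agrees with the SD rule on
  > 99% of individuals in large Gaussian cohorts.
* **Risk direction**: lower predicted height = higher predicted risk.
  In the pooled stratum, discrimination metrics and the odds ratio use the
  *sex-standardized* prediction (the analogue of a model including sex);
  within a single sex this is the same ranking, so the sex-specific rows
  are unaffected.
* **AUROC** is the rank-based Mann-Whitney estimator, ties counted half,
  verified against exhaustive pair enumeration on all small inputs.
* **AUPRC** is average precision — no interpolation between PR points —
  with ties resolved conservatively (within a tied block, positives rank
  after negatives).
* **OR per SD decrease** is `exp(-β)` from a maximum-likelihood logistic
  fit with Wald CI; complete separation raises an error advising the
  Firth-style penalized fallback (implemented as bias-reduced scoring,
  since no penalized-logistic package is part of the dependency set).
* **Nested LRT** uses the Gaussian-ML statistic `n·log(RSS₀/RSS₁)` with
  degrees of freedom equal to the rank added; redundant columns add zero
  of both.
* **CIs** are percentile bootstrap (default B = 2000; label-stratified
  resampling for discrimination metrics), seeded per stratum only, so
  identical prediction sets always produce identical report rows. The OR
  keeps its Wald interval.

A note on the combination claim: if the genetic score were the *exact*
additive genetic value and families shared no environment, mid-parental
height could add nothing — child height would be genetic value plus unique
environment. The improvement from combining the two predictors exists
precisely because realistic scores are imperfect (within-sex adjusted R²
near 0.38 for the best published height scores) and because families share
environment. The package's ordering tests therefore evaluate the
combination at study-matched score accuracy, and evaluate the
shared-environment mechanism with the exact oracle.

# Problem sizes and numerical choices

Test and demonstration runs are sized for a laptop-class single core:
closed-form checks use 50 000 trios × 400 loci (the resemblance statistics
depend on the variance parameters, not the locus count, once the score is
polygenic); the end-to-end construction property uses 6 400 founders ×
1 000 loci split 0.625 / 0.125 / 0.25; bootstrap-coverage checks use 200
datasets of n = 400 with B = 300. The demonstration experiment in
`scripts/acceptance.R` simulates 3 000 families — the scale of the
genotyped evaluation cohort this mirrors — with 4 000 fully causal loci,
chosen so the constructed score's within-sex accuracy lands in the regime
reported for the best published height scores (expected
R² ≈ h²/(1 + M/(n·h²)) ≈ 0.38 at training n ≈ 4 800).

Degenerate inputs are contracts, not surprises: constant-dosage variants
are flagged and excluded with a p = 1 convention; empty clump survivor
sets warn and yield empty scores; zero harmonized variants, single-class
labels, zero reference SD and non-nested designs are hard errors;
half-year age rounding sends exact quarter-year ties up.

# Limitations

The simulator omits linkage disequilibrium (beyond duplicated columns for
clumping tests), X-chromosome dosage, pubertal-timing heterogeneity,
population structure and non-European allele-frequency spectra. Passing
tests therefore demonstrate correctness of the estimators and the
qualitative orderings under the stated model — not transferability of any
particular score to real cohorts, where LD, ascertainment, measurement
error in parental heights, and ancestry effects all bite. The Khamis-Roche
coefficient table ships as an editable TSV: for real use the published
coefficients must be transcribed into it; all packaged analyses fit an
analogous table on synthetic training children instead.
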