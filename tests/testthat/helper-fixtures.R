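# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Small default cohort with growth, used across modules.
small_sim <- function() {
  cached("small_sim", function() {
    simulate_trio_cohort(sim_params(n_families = 500, n_loci = 120,
                                    seed = 11), growth = TRUE)
  })
}

# Tiny genotype panel with hand-set alleles, for scoring tests.
tiny_panel <- function(dosages, effect = NULL, other = NULL, freq = NULL) {
  L <- ncol(dosages)
  if (is.null(effect)) effect <- rep("A", L)
  if (is.null(other)) other <- rep("G", L)
  if (is.null(freq)) freq <- rep(0.5, L)
  if (is.null(colnames(dosages)))
    colnames(dosages) <- sprintf("rs%03d", seq_len(L))
  if (is.null(rownames(dosages)))
    rownames(dosages) <- sprintf("s%03d", seq_len(nrow(dosages)))
  genotype_matrix(dosages, data.frame(
    id = colnames(dosages), chr = "1", pos = seq_len(L) * 100L,
    effect_allele = effect, other_allele = other, freq = freq,
    stringsAsFactors = FALSE))
}

# Exhaustive pairwise AUROC oracle: P(score_pos > score_neg) + 0.5 ties.
auroc_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Minimal scoring-file text.
write_toy_scoring_file <- function(path, rsid = TRUE) {
  lines <- c("### toy", "#pgs_name=toy_score", "#genome_build=simulated")
  if (rsid) {
    lines <- c(lines,
               "rsID\teffect_allele\tother_allele\teffect_weight",
               "rs001\tA\tG\t0.25",
               "rs002\tC\tT\t-0.10")
  } else {
    lines <- c(lines,
               "chr_name\tchr_position\teffect_allele\tother_allele\teffect_weight",
               "1\t100\tA\tG\t0.25",
               "2\t200\tC\tT\t-0.10")
  }
  writeLines(lines, path)
  path
}
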