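#' @keywords internal
"_PACKAGE"

# Shared input-checking helpers. All user-facing errors go through stop()
# with call. = FALSE so messages read as package errors, not internals.

.assert <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
}

.is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

.is_prob <- function(x, open_left = FALSE, open_right = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x)) return(FALSE)
  lo <- if (open_left) x > 0 else x >= 0
  hi <- if (open_right) x < 1 else x <= 1
  lo && hi
}

# Normalize sex coding to a factor with levels female/male.
.norm_sex <- function(sex) {
  if (is.factor(sex)) sex <- as.character(sex)
  s <- tolower(as.character(sex))
  s[s %in% c("f", "female", "girl", "2")] <- "female"
  s[s %in% c("m", "male", "boy", "1")] <- "male"
  bad <- !s %in% c("female", "male") & !is.na(s)
  .assert(!any(bad), paste0(
    "unrecognized sex code(s): ", paste(unique(sex[bad]), collapse = ", ")))
  factor(s, levels = c("female", "male"))
}

# Draw a seed for a named sub-stage from the current RNG stream so that a
# single top-level seed determines every stage reproducibly.
.derive_seed <- function() {
  sample.int(.Machine$integer.max, 1L)
}

# Write a data.frame as TSV with empty strings for NA (round-trips through
# .read_tsv below).
.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

.read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", na.strings = c("", "NA"),
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}
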