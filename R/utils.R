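# shared internal helpers: seeded RNG, sequence primitives, validation

DNA_BASES <- c("A", "C", "G", "T")

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Deterministic child seed for stage `i` of a multi-stage simulation;
# arithmetic in doubles (exact below 2^53), result within 32-bit range.
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(i) * 9176) %% 2147483647)
}

#' Reverse complement of DNA strings
#'
#' Strict-base reverse complement of one or more DNA strings (A/C/G/T plus
#' IUPAC ambiguity codes, as supported by Biostrings).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @examples
#' revcomp("ACGTT")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# All length-k windows of a sequence as a character vector (forward strand).
seq_windows <- function(sequence, k) {
  n <- nchar(sequence)
  if (n < k) return(character(0))
  substring(sequence, 1:(n - k + 1), k:n)
}

assert_scalar_prob <- function(x, name, lower = 0, upper = 1,
                               lower_open = FALSE, upper_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name))
  }
  lo_ok <- if (lower_open) x > lower else x >= lower
  hi_ok <- if (upper_open) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` must be in %s%g, %g%s (got %g).", name,
      if (lower_open) "(" else "[", lower, upper,
      if (upper_open) ")" else "]", x
    ))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
      x != trunc(x)) {
    abort(sprintf("`%s` must be an integer >= %d (got %s).", name, min,
                  paste(x, collapse = ",")))
  }
  invisible(as.integer(x))
}

# Named completeness/carriage vector aligned to `ids`, clamped to
# [eps, 1 - eps] so log-likelihoods stay finite.
clamp_prob <- function(p, eps = 1e-3) pmin(pmax(p, eps), 1 - eps)

# Accept completeness either as a named numeric vector (values in (0, 1]) or
# as a data frame with genome_id + completeness columns (percent or fraction).
completeness_vector <- function(completeness, genome_ids) {
  if (is.data.frame(completeness)) {
    stopifnot(all(c("genome_id", "completeness") %in% names(completeness)))
    v <- setNames(completeness$completeness, completeness$genome_id)
  } else if (is.numeric(completeness) && !is.null(names(completeness))) {
    v <- completeness
  } else if (is.numeric(completeness) && length(completeness) == 1) {
    v <- setNames(rep(completeness, length(genome_ids)), genome_ids)
  } else {
    abort("`completeness` must be a named numeric vector, a single value, or a data frame with genome_id and completeness columns.")
  }
  missing <- setdiff(genome_ids, names(v))
  if (length(missing) > 0) {
    abort(paste0("completeness missing for genomes: ",
                 paste(missing, collapse = ", ")))
  }
  v <- v[genome_ids]
  if (any(v > 1)) v <- v / 100  # percent scale
  if (any(v <= 0 | v > 1)) abort("completeness values must be in (0, 1] (or (0, 100] percent).")
  v
}
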