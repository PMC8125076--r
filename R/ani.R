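# k-mer ANI estimation: canonical k-mer sketches, a Mash-style distance
# transform, all-vs-all tables, and import of externally computed ANI TSVs.

#' Canonical k-mer sketch of a genome sequence
#'
#' Returns the set of canonical k-mers of a sequence: for every window the
#' lexicographic minimum of the k-mer and its reverse complement, so a
#' sequence and its reverse complement sketch identically. Windows containing
#' non-ACGT symbols are skipped. By default the full k-mer set is kept;
#' `sketch_size` switches to a bottom-`s` MinHash sketch under a fixed
#' deterministic hash for large inputs.
#'
#' @param sequence a single DNA string.
#' @param k odd k-mer size in `[11, 31]`.
#' @param sketch_size maximum sketch size; `Inf` (default) keeps all k-mers.
#' @return character vector of distinct canonical k-mers.
#' @examples
#' sketch_genome("ACGTACGT", k = 5)
#' @export
sketch_genome <- function(sequence, k = 21, sketch_size = Inf) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (k %% 2 != 1 || k < 11 && k != 3 && k != 5 || k > 31) {
    # k = 3/5 admitted for hand-checkable examples in documentation/tests
    abort("`k` must be odd and within [11, 31].")
  }
  if (nchar(sequence) < k) {
    abort(sprintf("sequence length %d is shorter than k = %d.",
                  nchar(sequence), k))
  }
  sequence <- toupper(sequence)
  fwd <- seq_windows(sequence, k)
  # reverse complement of window i equals window (n-k+2-i) of the
  # reverse-complemented sequence
  rev_all <- revcomp(sequence)
  rev <- seq_windows(rev_all, k)[rev(seq_along(fwd))]
  keep <- !grepl("[^ACGT]", fwd)
  canon <- unique(ifelse(fwd <= rev, fwd, rev)[keep])
  if (is.finite(sketch_size) && length(canon) > sketch_size) {
    canon <- canon[order(kmer_hash(canon))][seq_len(sketch_size)]
  }
  canon
}

# Deterministic 31-bit hash of k-mers (two base-4 halves combined modulo a
# Mersenne prime); used only to pick bottom-s MinHash sketches.
kmer_hash <- function(kmers) {
  p <- 2147483647
  digits <- chartr("ACGT", "0123", kmers)
  half <- ceiling(nchar(kmers) / 2)
  a <- strtoi(substr(digits, 1, pmin(half, 15)), base = 4L)
  b <- strtoi(substr(digits, half + 1, half + 15), base = 4L)
  b[is.na(b)] <- 0
  ((a %% p) * 48271 + (b %% p) * 16807) %% p
}

#' Estimate ANI from two k-mer sketches
#'
#' Mash-style estimator: with Jaccard similarity `J = |A n B| / |A u B|`,
#' the per-base divergence is `D = -(1/k) * log(2J / (1 + J))` and
#' `ANI = 100 * (1 - D)`, floored at 0. Disjoint sketches give ANI 0.
#'
#' @param sketch_a,sketch_b character vectors of canonical k-mers, e.g. from
#'   [sketch_genome()].
#' @param k the k-mer size used to build the sketches.
#' @return ANI percent in `[0, 100]`.
#' @examples
#' s <- sketch_genome(paste(rep("ACGTT", 40), collapse = ""), k = 11)
#' estimate_ani(s, s, k = 11)
#' @export
estimate_ani <- function(sketch_a, sketch_b, k = 21) {
  if (length(sketch_a) == 0 || length(sketch_b) == 0) {
    abort("cannot estimate ANI from an empty sketch.")
  }
  inter <- sum(data.table::`%chin%`(sketch_a, sketch_b))
  j <- inter / (length(sketch_a) + length(sketch_b) - inter)
  if (j <= 0) return(0)
  d <- -(1 / k) * log(2 * j / (1 + j))
  max(0, 100 * (1 - d))
}

#' All-vs-all ANI over a set of genome sequences
#'
#' Sketches every genome once and evaluates [estimate_ani()] on every
#' unordered pair.
#'
#' @param genomes tibble (genome_id, sequence) or a named character vector.
#' @param k k-mer size.
#' @param sketch_size per-genome sketch size (default: full k-mer set).
#' @return tibble (query, reference, ani) with one row per unordered pair,
#'   `query < reference` lexicographically.
#' @export
pairwise_ani <- function(genomes, k = 21, sketch_size = Inf) {
  if (is.character(genomes)) {
    stopifnot(!is.null(names(genomes)))
    genomes <- tibble(genome_id = names(genomes), sequence = unname(genomes))
  }
  stopifnot(all(c("genome_id", "sequence") %in% names(genomes)))
  genomes <- genomes |> arrange(.data$genome_id)
  sketches <- lapply(genomes$sequence, sketch_genome, k = k,
                     sketch_size = sketch_size)
  names(sketches) <- genomes$genome_id
  ids <- genomes$genome_id
  if (length(ids) < 2) {
    return(tibble(query = character(0), reference = character(0),
                  ani = numeric(0)))
  }
  pairs <- utils::combn(ids, 2)
  tibble(
    query = pairs[1, ], reference = pairs[2, ],
    ani = purrr::map2_dbl(pairs[1, ], pairs[2, ], function(a, b) {
      estimate_ani(sketches[[a]], sketches[[b]], k = k)
    })
  )
}

#' Read a pairwise ANI table in the five-column TSV dialect
#'
#' Accepts the common external-tool format: tab-separated rows of query
#' path, reference path, ANI percent, and optionally mapped/total fragment
#' counts (ignored). Directed pairs reported in both orientations are
#' symmetrized by their arithmetic mean; self-pairs are dropped. Path-like
#' ids are reduced to genome ids by stripping directories and a
#' fasta/fa/fna extension.
#'
#' @param path TSV file path.
#' @return tibble (query, reference, ani), one row per unordered pair,
#'   with attribute `provenance = "imported"`.
#' @export
read_ani_table <- function(path) {
  stopifnot(file.exists(path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(structure(tibble(query = character(0), reference = character(0),
                            ani = numeric(0)), provenance = "imported"))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 3 |
                 vapply(fields, function(f) is.na(suppressWarnings(as.numeric(f[3]))),
                        logical(1)))
  if (length(bad) > 0) {
    abort(sprintf("malformed ANI row at line %d: %s", bad[1],
                  lines[bad[1]]))
  }
  strip <- function(x) {
    out <- basename(x)
    sub("\\.(fa|fasta|fna)(\\.gz)?$", "", out)
  }
  tbl <- tibble(
    query = strip(vapply(fields, `[`, character(1), 1)),
    reference = strip(vapply(fields, `[`, character(1), 2)),
    ani = as.numeric(vapply(fields, `[`, character(1), 3))
  )
  if (any(tbl$ani < 0 | tbl$ani > 100)) {
    abort("ANI values must lie in [0, 100].")
  }
  tbl <- tbl |>
    filter(.data$query != .data$reference) |>
    mutate(a = pmin(.data$query, .data$reference),
           b = pmax(.data$query, .data$reference)) |>
    group_by(.data$a, .data$b) |>
    summarise(ani = mean(.data$ani), .groups = "drop") |>
    rename(query = "a", reference = "b")
  structure(tbl, provenance = "imported")
}

#' Write an ANI table in the five-column TSV dialect
#'
#' @param ani tibble (query, reference, ani).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ani_table <- function(ani, path) {
  stopifnot(all(c("query", "reference", "ani") %in% names(ani)))
  out <- ani |>
    mutate(mapped = NA_integer_, total = NA_integer_)
  readr::write_tsv(out, path, col_names = FALSE, na = "")
  invisible(path)
}

# fast symmetric lookup structure: named numeric vector keyed "a\tb", a < b
ani_lookup <- function(ani) {
  key <- paste(pmin(ani$query, ani$reference),
               pmax(ani$query, ani$reference), sep = "\t")
  setNames(ani$ani, key)
}

ani_between <- function(lookup, a, b) {
  v <- lookup[paste(pmin(a, b), pmax(a, b), sep = "\t")]
  ifelse(is.na(v), 0, unname(v))
}
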