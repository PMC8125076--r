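# Abundance and occupancy profiling: subsampled, 100%-identity competitive
# read assignment to mOTUs, per-metagenome normalization, per-location
# averaging and the presence cutoff.

#' Subsample a read set without replacement
#'
#' @param reads tibble with one row per read (e.g. from [generate_reads()]
#'   or [read_fastq()]).
#' @param target target number of reads (default 1,000,000). When the
#'   library is smaller than the target all reads are returned with a
#'   warning.
#' @param seed integer seed.
#' @return tibble of `min(target, nrow(reads))` rows.
#' @export
subsample_reads <- function(reads, target = 1e6, seed = 1) {
  assert_count(target, "target", min = 1)
  stopifnot(is.data.frame(reads))
  if (nrow(reads) == 0) abort("cannot subsample an empty read set.")
  if (nrow(reads) < target) {
    warn(sprintf("library has %d reads, below the %d-read target; using all.",
                 nrow(reads), as.integer(target)))
    return(reads)
  }
  with_seed(seed, reads[sample.int(nrow(reads), target), , drop = FALSE])
}

#' Build an exact-match read index over a genome collection
#'
#' Supports the 100%-identity mapping criterion: a read maps to a genome iff
#' it occurs as an exact, full-length substring of the genome on either
#' strand (zero mismatches, no clipping). The index is a hashed set of every
#' read-length window of each genome and of its reverse complement.
#'
#' @param genomes named character vector of genome sequences, or a tibble
#'   (genome_id, sequence).
#' @param read_length the fixed read length the index answers for (>= 31).
#' @return a `match_index` object for [match_reads()].
#' @export
build_match_index <- function(genomes, read_length = 150) {
  if (is.data.frame(genomes)) {
    stopifnot(all(c("genome_id", "sequence") %in% names(genomes)))
    genomes <- setNames(genomes$sequence, genomes$genome_id)
  }
  stopifnot(is.character(genomes), !is.null(names(genomes)))
  assert_count(read_length, "read_length", min = 31)
  short <- names(genomes)[nchar(genomes) < read_length]
  if (length(short) > 0) {
    warn(paste0("genomes shorter than the read length can never match ",
                "full-length reads: ", paste(short, collapse = ", ")))
  }
  windows <- lapply(genomes, function(s) {
    unique(c(seq_windows(s, read_length),
             seq_windows(revcomp(s), read_length)))
  })
  structure(list(windows = windows, read_length = read_length,
                 genome_ids = names(genomes)),
            class = "match_index")
}

#' @export
print.match_index <- function(x, ...) {
  cat(sprintf("<match_index> %d genomes, read length %d\n",
              length(x$genome_ids), x$read_length))
  invisible(x)
}

#' Find all genomes containing each read as an exact substring
#'
#' @param index a `match_index` from [build_match_index()].
#' @param reads character vector of read sequences, or a tibble with a
#'   `sequence` column; all reads must have the index's read length.
#' @return list (one element per read) of character vectors of matching
#'   genome ids; empty vector = unmapped.
#' @export
match_reads <- function(index, reads) {
  stopifnot(inherits(index, "match_index"))
  if (is.data.frame(reads)) reads <- reads$sequence
  stopifnot(is.character(reads))
  if (length(reads) == 0) return(list())
  if (!all(nchar(reads) == index$read_length)) {
    abort(sprintf("all reads must have length %d (the index read length).",
                  index$read_length))
  }
  hit_mat <- vapply(index$windows, function(w) {
    data.table::`%chin%`(reads, w)
  }, logical(length(reads)))
  if (length(reads) == 1) hit_mat <- matrix(hit_mat, nrow = 1,
                                            dimnames = list(NULL, index$genome_ids))
  apply(hit_mat, 1, function(row) index$genome_ids[row], simplify = FALSE)
}

#' Competitively assign matched reads to mOTUs
#'
#' A read matching genomes of exactly one mOTU counts 1 for that mOTU.
#' A read matching genomes spanning k > 1 mOTUs is, by default, split
#' equally (1/k each), which conserves total counts; alternatives discard
#' such reads or assign them to a single mOTU uniformly at random.
#' Fractional counts always satisfy
#' `sum(motu counts) + unmapped = number of reads` (for `ambiguous =
#' "discard"`, discarded reads are tallied separately so the identity still
#' closes).
#'
#' @param matches per-read genome-id sets from [match_reads()].
#' @param genome_to_motu named character vector (genome_id -> motu_id) or a
#'   `motu_catalog`; every matchable genome must have an mOTU.
#' @param ambiguous cross-mOTU multi-matcher policy: "split" (default),
#'   "discard", or "random".
#' @param seed seed for `ambiguous = "random"`.
#' @return tibble (motu_id, count) including the pseudo-rows `"unmapped"`
#'   and, under "discard", `"discarded"`.
#' @export
competitive_assign <- function(matches, genome_to_motu,
                               ambiguous = c("split", "discard", "random"),
                               seed = 1) {
  ambiguous <- match.arg(ambiguous)
  if (is.data.frame(genome_to_motu)) {
    cat_tbl <- as_tibble(genome_to_motu) |> filter(!is.na(.data$motu_id))
    genome_to_motu <- setNames(cat_tbl$motu_id, cat_tbl$genome_id)
  }
  stopifnot(is.character(genome_to_motu), !is.null(names(genome_to_motu)))

  motu_sets <- lapply(matches, function(gs) {
    if (length(gs) == 0) return(character(0))
    if (!all(gs %in% names(genome_to_motu))) {
      abort(paste0("matched genome(s) without an mOTU assignment: ",
                   paste(setdiff(gs, names(genome_to_motu)), collapse = ", ")))
    }
    unique(unname(genome_to_motu[gs]))
  })

  counts <- numeric(0)
  add <- function(counts, id, w) {
    counts[id] <- (if (id %in% names(counts)) counts[[id]] else 0) + w
    counts
  }
  if (ambiguous == "random") {
    rng <- with_seed(seed, runif(length(motu_sets)))
  }
  for (i in seq_along(motu_sets)) {
    ms <- motu_sets[[i]]
    k <- length(ms)
    if (k == 0) {
      counts <- add(counts, "unmapped", 1)
    } else if (k == 1) {
      counts <- add(counts, ms, 1)
    } else if (ambiguous == "split") {
      for (m in ms) counts <- add(counts, m, 1 / k)
    } else if (ambiguous == "discard") {
      counts <- add(counts, "discarded", 1)
    } else {
      counts <- add(counts, sort(ms)[ceiling(rng[i] * k)], 1)
    }
  }
  tibble(motu_id = names(counts), count = unname(counts)) |>
    arrange(.data$motu_id)
}

#' Normalize per-mOTU read counts to relative abundances
#'
#' @param counts tibble (motu_id, count) from [competitive_assign()].
#' @param n_subsampled the number of reads assigned (the subsample size).
#' @return tibble (motu_id, abundance) with abundance = count /
#'   n_subsampled; pseudo-rows (unmapped/discarded) keep their labels.
#' @export
relative_abundance <- function(counts, n_subsampled) {
  assert_count(n_subsampled, "n_subsampled", min = 1)
  if (sum(counts$count) > n_subsampled + 1e-9) {
    abort("counts exceed the number of subsampled reads.")
  }
  counts |> mutate(abundance = .data$count / n_subsampled) |>
    select("motu_id", "abundance")
}

#' Profile mOTU relative abundance across metagenome samples
#'
#' Full per-sample pipeline: subsample each library, match reads at 100%
#' identity against all catalog genomes, competitively assign to mOTUs and
#' normalize per metagenome. Genomes excluded from the catalog are not
#' indexed.
#'
#' @param reads named list (sample_id -> read tibble with a `sequence`
#'   column).
#' @param genomes named character vector (or tibble) of genome sequences.
#' @param catalog a `motu_catalog` (or named genome_id -> motu_id vector).
#' @param subsample subsample size per library (default 1,000,000).
#' @param read_length read length; inferred from the first read when `NULL`.
#' @param ambiguous cross-mOTU multi-match policy; see
#'   [competitive_assign()].
#' @param seed integer seed (per-sample child seeds are derived from it).
#' @return an `abundance_matrix`: long tibble (sample_id, motu_id,
#'   abundance) including an `"unmapped"` row per sample; attributes record
#'   the subsample size and seed.
#' @export
profile_abundance <- function(reads, genomes, catalog, subsample = 1e6,
                              read_length = NULL,
                              ambiguous = "split", seed = 1) {
  stopifnot(is.list(reads), !is.null(names(reads)))
  if (is.data.frame(genomes)) {
    genomes <- setNames(genomes$sequence, genomes$genome_id)
  }
  if (is.data.frame(catalog)) {
    keep <- as_tibble(catalog) |> filter(!is.na(.data$motu_id))
    map <- setNames(keep$motu_id, keep$genome_id)
  } else {
    map <- catalog
  }
  genomes <- genomes[names(genomes) %in% names(map)]
  if (length(genomes) == 0) abort("no catalog genome has a sequence.")
  if (is.null(read_length)) {
    read_length <- nchar(reads[[1]]$sequence[1])
  }
  index <- build_match_index(genomes, read_length = read_length)

  cols <- purrr::imap(reads, function(rd, sid) {
    sub <- subsample_reads(rd, target = subsample,
                           seed = child_seed(seed, match(sid, names(reads))))
    counts <- competitive_assign(match_reads(index, sub), map,
                                 ambiguous = ambiguous,
                                 seed = child_seed(seed, 5000 + match(sid, names(reads))))
    relative_abundance(counts, nrow(sub)) |>
      mutate(sample_id = sid)
  })
  out <- bind_rows(cols) |>
    select("sample_id", "motu_id", "abundance")
  structure(out, class = c("abundance_matrix", class(tibble())),
            subsample = subsample, seed = seed)
}

#' Average sample abundances per location into an occupancy table
#'
#' Unweighted arithmetic mean over all samples of a site, counting samples
#' where an mOTU was not observed as zeros.
#'
#' @param abundance long tibble (sample_id, motu_id, abundance), e.g. from
#'   [profile_abundance()]; `"unmapped"` rows are dropped.
#' @param samples sample metadata tibble with `sample_id` and `site_id`
#'   columns (region/country/continent carried through when present).
#' @return tibble (motu_id, site_id, mean_abundance, n_samples).
#' @export
aggregate_by_location <- function(abundance, samples) {
  stopifnot(all(c("sample_id", "motu_id", "abundance") %in% names(abundance)))
  stopifnot(all(c("sample_id", "site_id") %in% names(samples)))
  missing <- setdiff(unique(abundance$sample_id), samples$sample_id)
  if (length(missing) > 0) {
    abort(paste0("samples without metadata: ", paste(missing, collapse = ", ")))
  }
  ab <- as_tibble(abundance) |> filter(.data$motu_id != "unmapped",
                                       .data$motu_id != "discarded")
  site_of <- samples |> distinct(.data$sample_id, .data$site_id)
  n_per_site <- site_of |>
    filter(.data$sample_id %in% unique(abundance$sample_id)) |>
    dplyr::count(.data$site_id, name = "n_samples")
  # complete the grid so absent (mOTU, sample) pairs average in as zeros
  full <- tidyr::expand_grid(
    motu_id = sort(unique(ab$motu_id)),
    sample_id = sort(unique(abundance$sample_id))
  ) |>
    left_join(ab, by = c("motu_id", "sample_id")) |>
    mutate(abundance = tidyr::replace_na(.data$abundance, 0)) |>
    left_join(site_of, by = "sample_id")
  full |>
    group_by(.data$motu_id, .data$site_id) |>
    summarise(mean_abundance = mean(.data$abundance), .groups = "drop") |>
    left_join(n_per_site, by = "site_id") |>
    arrange(.data$motu_id, .data$site_id)
}

#' Flag mOTU presence per site at an abundance cutoff
#'
#' @param occupancy tibble (motu_id, site_id, mean_abundance, ...) from
#'   [aggregate_by_location()].
#' @param cutoff presence cutoff on mean relative abundance, default 0.0003
#'   (0.03%); comparison is inclusive (>=).
#' @return the occupancy tibble with a logical `present` column and the
#'   cutoff stored as an attribute.
#' @export
apply_presence_cutoff <- function(occupancy, cutoff = 0.0003) {
  assert_scalar_prob(cutoff, "cutoff", lower_open = TRUE, upper_open = TRUE)
  stopifnot(all(c("motu_id", "site_id", "mean_abundance") %in%
                  names(occupancy)))
  structure(
    occupancy |> mutate(present = .data$mean_abundance >= cutoff),
    cutoff = cutoff
  )
}

#' @exportS3Method generics::glance
glance.abundance_matrix <- function(x, ...) {
  per_sample <- as_tibble(x) |>
    group_by(.data$sample_id) |>
    summarise(total = sum(.data$abundance),
              unmapped = sum(.data$abundance[.data$motu_id == "unmapped"]),
              .groups = "drop")
  tibble(
    n_samples = nrow(per_sample),
    n_motus = dplyr::n_distinct(x$motu_id[x$motu_id != "unmapped"]),
    mean_unmapped = mean(per_sample$unmapped),
    max_mass_balance_error = max(abs(per_sample$total - 1)),
    subsample = attr(x, "subsample")
  )
}

#' Heatmap of mOTU relative abundance by sample
#'
#' @param object an `abundance_matrix` from [profile_abundance()].
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.abundance_matrix <- function(object, ...) {
  df <- as_tibble(object) |> filter(.data$motu_id != "unmapped")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$motu_id,
                                   fill = .data$abundance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(trans = "sqrt") +
    ggplot2::labs(x = "metagenome sample", y = "mOTU",
                  fill = "relative\nabundance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
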