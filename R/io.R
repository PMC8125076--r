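# File-format glue: FASTA/FASTQ via Biostrings, TSV via readr.

#' Write genome sequences to FASTA
#'
#' One multi-record FASTA per genome (`<genome_id>.fasta` under `dir`), or a
#' single combined file when `combined` names a path.
#'
#' @param sequences named character vector of genome sequences.
#' @param dir output directory (created if needed).
#' @param combined optional path for one combined FASTA instead.
#' @return the written path(s), invisibly.
#' @export
write_genomes <- function(sequences, dir = NULL, combined = NULL) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  set <- Biostrings::DNAStringSet(sequences)
  if (!is.null(combined)) {
    Biostrings::writeXStringSet(set, combined)
    return(invisible(combined))
  }
  stopifnot(!is.null(dir))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(sequences), function(g) {
    p <- file.path(dir, paste0(g, ".fasta"))
    Biostrings::writeXStringSet(set[g], p)
    p
  }, character(1))
  invisible(unname(paths))
}

#' Read genome FASTA files
#'
#' @param paths FASTA file paths or a directory (all `.fa/.fasta/.fna`
#'   inside). Multi-record files are concatenated per file; the genome id
#'   is the file name without extension.
#' @return named character vector of genome sequences.
#' @export
read_genomes <- function(paths) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.(fa|fasta|fna)$",
                        full.names = TRUE)
  }
  stopifnot(length(paths) > 0)
  out <- vapply(paths, function(p) {
    set <- Biostrings::readDNAStringSet(p)
    paste(as.character(set), collapse = "")
  }, character(1))
  setNames(out, tools::file_path_sans_ext(basename(paths)))
}

#' Write reads to FASTQ (fixed quality symbol)
#'
#' @param reads read tibble (read_id, sequence).
#' @param path output FASTQ path.
#' @param quality_char constant per-base quality symbol (default "I",
#'   Phred 40).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  set <- Biostrings::DNAStringSet(reads$sequence)
  names(set) <- reads$read_id
  qual <- Biostrings::BStringSet(strrep(quality_char, nchar(reads$sequence)))
  Biostrings::writeXStringSet(set, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a FASTQ file into a read tibble
#'
#' @param path FASTQ path.
#' @return tibble (read_id, sequence).
#' @export
read_fastq <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(read_id = names(set), sequence = unname(as.character(set)))
}

#' Read / write a 0/1 gene presence matrix TSV
#'
#' Rows are gene clusters, columns genome ids, cells 0/1; first column
#' `gene`.
#'
#' @param path TSV path.
#' @return [read_presence_tsv()]: a wide presence tibble.
#' @export
read_presence_tsv <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot("gene" %in% names(tbl))
  tbl |> mutate(across(-"gene", as.integer))
}

#' @param presence wide presence tibble (see [presence_matrix()]).
#' @rdname read_presence_tsv
#' @export
write_presence_tsv <- function(presence, path) {
  readr::write_tsv(presence, path)
  invisible(path)
}

#' Read genome or sample metadata TSV
#'
#' Thin readr wrapper kept for a stable interface; expects at least the id
#' column named in `id`.
#'
#' @param path TSV path with header.
#' @param id required id column name.
#' @return tibble.
#' @export
read_metadata_tsv <- function(path, id = "genome_id") {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  if (!id %in% names(tbl)) {
    abort(sprintf("metadata file lacks the `%s` column.", id))
  }
  tbl
}

#' Write an mOTU catalog as TSV and/or nested JSON
#'
#' @param catalog a `motu_catalog`.
#' @param tsv,json output paths (either may be `NULL`).
#' @return written paths, invisibly.
#' @export
write_catalog <- function(catalog, tsv = NULL, json = NULL) {
  written <- character(0)
  if (!is.null(tsv)) {
    readr::write_tsv(as_tibble(catalog), tsv)
    written <- c(written, tsv)
  }
  if (!is.null(json)) {
    rlang::check_installed("jsonlite")
    df <- as_tibble(catalog) |> filter(!is.na(.data$motu_id))
    nested <- lapply(split(df, df$motu_id), function(d) {
      list(members = d$genome_id,
           representative = d$genome_id[d$is_representative][1],
           tiers = setNames(as.list(d$tier), d$genome_id))
    })
    jsonlite::write_json(nested, json, auto_unbox = TRUE, pretty = TRUE)
    written <- c(written, json)
  }
  invisible(written)
}
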