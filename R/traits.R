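# Marker-gene trait matrices (core / accessory / absent per mOTU) and
# cosmopolitan / regional / endemic biogeography classification.

#' Filter marker-gene hits into per-genome marker presence
#'
#' A marker is present in a genome iff at least one hit passes both the
#' query-coverage threshold and the marker's identity threshold; both
#' comparisons are inclusive (>=). Defaults follow the conventional
#' protein-marker screen: 80% query coverage, 50% identity for all markers
#' except an 80% identity bar for PsaA-class markers.
#'
#' @param hits tibble (genome_id, marker, identity, coverage), e.g. from
#'   [read_hit_table()].
#' @param coverage_min minimum query coverage percent (default 80).
#' @param identity_default identity threshold percent applied to markers
#'   without an override (default 50).
#' @param identity_overrides named numeric vector of per-marker identity
#'   thresholds (default `c(PsaA = 80)`).
#' @return tibble (genome_id, marker) of passing marker calls, one row per
#'   genome/marker pair.
#' @examples
#' hits <- tibble::tibble(genome_id = "g1", marker = c("Sqr", "PsaA"),
#'                        identity = c(55, 79.9), coverage = c(90, 95))
#' filter_hits(hits)
#' @export
filter_hits <- function(hits, coverage_min = 80, identity_default = 50,
                        identity_overrides = c(PsaA = 80)) {
  stopifnot(all(c("genome_id", "marker", "identity", "coverage")
                %in% names(hits)))
  if (any(hits$identity < 0 | hits$identity > 100) ||
      any(hits$coverage < 0 | hits$coverage > 100)) {
    abort("identity and coverage must be percentages in [0, 100].")
  }
  um <- unique(hits$marker)
  thresholds <- tibble(
    marker = um,
    identity_min = ifelse(um %in% names(identity_overrides),
                          unname(identity_overrides[um]),
                          identity_default)
  )
  if (any(is.na(thresholds$identity_min))) {
    abort(paste0("no identity threshold for marker(s): ",
                 paste(thresholds$marker[is.na(thresholds$identity_min)],
                       collapse = ", ")))
  }
  hits |>
    left_join(thresholds, by = "marker") |>
    filter(.data$coverage >= coverage_min,
           .data$identity >= .data$identity_min) |>
    distinct(.data$genome_id, .data$marker) |>
    arrange(.data$genome_id, .data$marker)
}

#' Read a marker hit table (pre-reduced or 12-column alignment format)
#'
#' Accepts either the pre-reduced 4-column TSV (genome_id, marker,
#' identity, coverage) or the standard 12-column tabular alignment dialect
#' (query id, subject id, percent identity, alignment length, mismatches,
#' gap opens, qstart, qend, sstart, send, e-value, bit score). For the
#' 12-column form the query id is the genome, the subject id is the marker,
#' and query coverage is derived as `100 * (qend - qstart + 1) /
#' query_length`, requiring a `query_lengths` table.
#'
#' @param path TSV path (no header for the 12-column form; a header
#'   `genome_id  marker  identity  coverage` is accepted for the 4-column
#'   form).
#' @param query_lengths tibble (query_id, length); required for 12-column
#'   input.
#' @return tibble (genome_id, marker, identity, coverage).
#' @export
read_hit_table <- function(path, query_lengths = NULL) {
  stopifnot(file.exists(path))
  first <- readr::read_lines(path, n_max = 1)
  n_col <- length(strsplit(first, "\t", fixed = TRUE)[[1]])
  if (n_col >= 12) {
    cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
              "qstart", "qend", "sstart", "send", "evalue", "bitscore")
    tbl <- readr::read_tsv(path, col_names = cols, show_col_types = FALSE)
    if (is.null(query_lengths)) {
      abort("12-column hit tables need `query_lengths` (query_id, length) to derive query coverage.")
    }
    tbl |>
      left_join(query_lengths, by = c(qseqid = "query_id")) |>
      mutate(coverage = 100 * (.data$qend - .data$qstart + 1) / .data$length.y) |>
      select(genome_id = "qseqid", marker = "sseqid",
             identity = "pident", "coverage")
  } else if (n_col == 4) {
    has_header <- grepl("genome_id", first, fixed = TRUE)
    tbl <- readr::read_tsv(
      path, show_col_types = FALSE,
      col_names = if (has_header) TRUE else
        c("genome_id", "marker", "identity", "coverage")
    )
    tbl[, c("genome_id", "marker", "identity", "coverage")]
  } else {
    abort(sprintf("expected a 4- or 12-column hit table, found %d columns.",
                  n_col))
  }
}

#' Core / accessory / absent trait status of markers per mOTU
#'
#' Applies the absence evidence standard and the core/accessory likelihood
#' rule to marker genes. For each (mOTU, marker): if no member genome
#' carries the marker after filtering, the status is `absent`; otherwise
#' the marker's presence profile over the members is appended as an extra
#' gene row to the mOTU's observed presence context, and the decision rule
#' of [classify_genes()] (core iff the core-model log-likelihood exceeds
#' the accessory-model log-likelihood, with carriage probabilities taken
#' from the mOTU's fitted partition) sets the status.
#'
#' @param marker_presence tibble (genome_id, marker) of filtered marker
#'   calls from [filter_hits()]; member genomes missing from the table are
#'   treated (with a warning) as lacking every marker.
#' @param catalog a `motu_catalog`.
#' @param gene_content long tibble (genome_id, gene) of observed gene
#'   clusters providing the carriage context.
#' @param completeness per-genome completeness (named vector, fraction or
#'   percent, or metadata data frame).
#' @param markers optional character vector fixing the marker universe
#'   (defaults to the markers appearing in `marker_presence`).
#' @param ... passed to [classify_genes()].
#' @return tibble (motu_id, marker, status, loglik_core,
#'   loglik_accessory), status in {core, accessory, absent} (log-likelihoods
#'   are `NA` for absent markers).
#' @export
motu_traits <- function(marker_presence, catalog, gene_content, completeness,
                        markers = NULL, ...) {
  stopifnot(all(c("genome_id", "marker") %in% names(marker_presence)))
  markers <- markers %||% sort(unique(marker_presence$marker))
  members_tbl <- as_tibble(catalog) |> filter(!is.na(.data$motu_id))
  fits <- classify_by_motu(gene_content, catalog, completeness, ...)

  covered <- unique(marker_presence$genome_id)
  uncovered <- setdiff(members_tbl$genome_id, covered)
  if (length(uncovered) > 0 && nrow(marker_presence) > 0) {
    warn(paste0("catalog genomes absent from the marker table (treated as ",
                "carrying no markers): ", paste(uncovered, collapse = ", ")))
  }

  rows <- purrr::map(sort(unique(members_tbl$motu_id)), function(m) {
    ids <- sort(members_tbl$genome_id[members_tbl$motu_id == m])
    fit <- fits[[m]]
    c_i <- completeness_vector(completeness, ids)
    p_i <- fit$carriage[ids]
    purrr::map(markers, function(mk) {
      pres <- as.integer(ids %in%
        marker_presence$genome_id[marker_presence$marker == mk])
      if (sum(pres) == 0) {
        return(tibble(motu_id = m, marker = mk, status = "absent",
                      loglik_core = NA_real_, loglik_accessory = NA_real_))
      }
      llc <- loglik_core(pres, c_i)
      lla <- loglik_accessory(pres, p_i)
      tibble(motu_id = m, marker = mk,
             status = ifelse(llc > lla, "core", "accessory"),
             loglik_core = llc, loglik_accessory = lla)
    }) |> bind_rows()
  })
  out <- bind_rows(rows)
  structure(out, class = c("trait_matrix", class(tibble())))
}

#' Heatmap of marker trait status per mOTU
#'
#' Mirrors the conventional core/accessory/absent trait heatmap: one tile
#' per (mOTU, marker).
#'
#' @param object a `trait_matrix` from [motu_traits()].
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.trait_matrix <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$marker, y = .data$motu_id,
                                   fill = .data$status)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_manual(values = c(core = "#b2182b",
                                          accessory = "#fddbc7",
                                          absent = "white")) +
    ggplot2::labs(x = "marker gene", y = "mOTU", fill = "status") +
    ggplot2::theme_minimal()
}

#' Classify mOTU geographic distributions
#'
#' Combines two evidence channels — the source locations of an mOTU's
#' member genomes, and the sites where read-mapping occupancy flags the
#' mOTU present — into one location set per mOTU, then applies the rule
#' table: `cosmopolitan` when the evidence spans two or more continents;
#' `endemic` when it is confined to a single site or a single region;
#' `regional` otherwise (one continent, several regions); `unknown` when
#' there is no located evidence at all.
#'
#' @param catalog a `motu_catalog`.
#' @param genomes genome metadata tibble (genome_id, site, region, country,
#'   continent); continents come from the metadata, never from hardcoded
#'   geography.
#' @param occupancy optional occupancy table with a `present` column (from
#'   [apply_presence_cutoff()]).
#' @param sites site metadata (site_id, region, country, continent) used to
#'   locate occupancy evidence; required when `occupancy` is given.
#' @return tibble (motu_id, classification, n_continents, n_regions,
#'   n_sites, continents, regions, sites, continents_genomes,
#'   continents_reads) with location sets collapsed to comma-separated
#'   strings per channel.
#' @export
classify_biogeography <- function(catalog, genomes, occupancy = NULL,
                                  sites = NULL) {
  members_tbl <- as_tibble(catalog) |> filter(!is.na(.data$motu_id))
  loc_cols <- c("site", "region", "country", "continent")
  stopifnot(all(c("genome_id", loc_cols) %in% names(genomes)))

  genome_ev <- members_tbl |>
    left_join(genomes |> select("genome_id", all_of(loc_cols)),
              by = "genome_id") |>
    filter(!is.na(.data$site)) |>
    mutate(channel = "genomes") |>
    select("motu_id", "site", "region", "country", "continent", "channel")

  read_ev <- NULL
  if (!is.null(occupancy)) {
    stopifnot("present" %in% names(occupancy))
    if (is.null(sites)) {
      abort("`sites` metadata is required to locate occupancy evidence.")
    }
    stopifnot(all(c("site_id", "region", "country", "continent")
                  %in% names(sites)))
    read_ev <- as_tibble(occupancy) |>
      filter(.data$present) |>
      left_join(sites, by = "site_id") |>
      mutate(channel = "reads") |>
      select("motu_id", site = "site_id", "region", "country", "continent",
             "channel")
  }
  evidence <- bind_rows(genome_ev, read_ev)

  all_motus <- sort(unique(members_tbl$motu_id))
  out <- purrr::map(all_motus, function(m) {
    ev <- evidence |> filter(.data$motu_id == m)
    if (nrow(ev) == 0) {
      return(tibble(motu_id = m, classification = "unknown",
                    n_continents = 0L, n_regions = 0L, n_sites = 0L,
                    continents = "", regions = "", sites = "",
                    continents_genomes = "", continents_reads = ""))
    }
    conts <- sort(unique(ev$continent))
    regs <- sort(unique(ev$region))
    sts <- sort(unique(ev$site))
    cls <- if (length(conts) >= 2) {
      "cosmopolitan"
    } else if (length(sts) == 1 || length(regs) == 1) {
      "endemic"
    } else {
      "regional"
    }
    collapse <- function(x) paste(x, collapse = ",")
    tibble(
      motu_id = m, classification = cls,
      n_continents = length(conts), n_regions = length(regs),
      n_sites = length(sts),
      continents = collapse(conts), regions = collapse(regs),
      sites = collapse(sts),
      continents_genomes = collapse(sort(unique(
        ev$continent[ev$channel == "genomes"]))),
      continents_reads = collapse(sort(unique(
        ev$continent[ev$channel == "reads"])))
    )
  })
  bind_rows(out)
}
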