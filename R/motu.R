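# mOTU clustering: connected components over high-ANI genome pairs with
# two-tier completeness rules and low-completeness recruitment.

#' Cluster genomes into species-level mOTUs
#'
#' Implements the two-tier scheme: genomes passing the seed quality bar
#' (completeness >= `comp_seed_min`, contamination <= `contam_max`) form a
#' graph with edges wherever pairwise ANI exceeds `ani_threshold`; connected
#' components (singletons included) are the mOTUs. Less complete genomes
#' (`comp_recruit_min` <= completeness < `comp_seed_min`, contamination <=
#' `contam_max`) are recruited into an mOTU when their ANI to at least one of
#' its seed members exceeds the threshold. Everything else is retained but
#' marked excluded with a reason, never silently dropped.
#'
#' A recruit qualifying for more than one mOTU goes to the one with the
#' highest mean ANI to its seed members (pairs missing from the ANI table
#' count as 0); remaining ties break by lexicographic mOTU id. mOTU ids are
#' assigned by decreasing member count, then by lexicographically smallest
#' member id, as `mOTU01`, `mOTU02`, ...
#'
#' @param ani tibble (query, reference, ani) of pairwise ANI percentages,
#'   e.g. from [pairwise_ani()] or [read_ani_table()]; treated as symmetric.
#' @param genomes genome metadata tibble with at least `genome_id`,
#'   `completeness` (percent) and `contamination` (percent) columns.
#' @param ani_threshold ANI percent above which genomes are linked
#'   (default 95).
#' @param comp_seed_min minimum completeness (percent) for seed tier
#'   (default 70).
#' @param comp_recruit_min minimum completeness (percent) for recruitment
#'   (default 50).
#' @param contam_max maximum contamination percent (default 5).
#' @param ani_cmp comparison used against `ani_threshold`; the default
#'   `">"` links strictly-above-threshold pairs.
#' @return a `motu_catalog`: tibble (genome_id, motu_id, tier,
#'   is_representative, reason) where tier is one of seed/recruited/excluded
#'   and `motu_id` is `NA` for excluded genomes. Thresholds are stored as
#'   attributes.
#' @examples
#' ani <- tibble::tibble(query = c("A", "B"), reference = c("B", "C"),
#'                       ani = c(97, 96))
#' meta <- tibble::tibble(genome_id = c("A", "B", "C"),
#'                        completeness = c(95, 90, 85), contamination = 1)
#' cluster_motus(ani, meta)
#' @export
cluster_motus <- function(ani, genomes, ani_threshold = 95,
                          comp_seed_min = 70, comp_recruit_min = 50,
                          contam_max = 5, ani_cmp = `>`) {
  stopifnot(all(c("query", "reference", "ani") %in% names(ani)))
  stopifnot(all(c("genome_id", "completeness", "contamination")
                %in% names(genomes)))
  if (comp_recruit_min >= comp_seed_min) {
    abort("`comp_recruit_min` must be below `comp_seed_min`.")
  }
  if (anyDuplicated(genomes$genome_id)) abort("duplicate genome ids.")

  if (identical(attr(ani, "provenance"), "imported")) {
    covered <- union(ani$query, ani$reference)
    absent <- setdiff(genomes$genome_id, covered)
    if (length(absent) > 0) {
      warn(paste0("genomes absent from the imported ANI table (treated as ",
                  "having no above-threshold pairs): ",
                  paste(absent, collapse = ", ")))
    }
  }

  meta <- genomes |>
    mutate(tier = dplyr::case_when(
      .data$contamination > contam_max ~ "excluded",
      .data$completeness >= comp_seed_min ~ "seed",
      .data$completeness >= comp_recruit_min ~ "recruited",
      TRUE ~ "excluded"
    ),
    reason = dplyr::case_when(
      .data$contamination > contam_max ~ "high_contamination",
      .data$completeness < comp_recruit_min ~ "low_completeness",
      TRUE ~ NA_character_
    ))

  seeds <- meta$genome_id[meta$tier == "seed"]
  edges <- ani |>
    filter(ani_cmp(.data$ani, ani_threshold),
           .data$query %in% seeds, .data$reference %in% seeds,
           .data$query != .data$reference)
  g <- igraph::graph_from_data_frame(
    edges[, c("query", "reference")], directed = FALSE,
    vertices = data.frame(name = seeds)
  )
  comp <- igraph::components(g)$membership
  membership <- tibble(genome_id = names(comp), cluster = unname(comp))

  # recruitment of mid-completeness genomes
  lookup <- ani_lookup(ani)
  recruits <- meta$genome_id[meta$tier == "recruited"]
  recruit_rows <- purrr::map(recruits, function(r) {
    by_cluster <- membership |>
      mutate(ani = ani_between(lookup, .data$genome_id, r)) |>
      group_by(.data$cluster) |>
      summarise(best = max(.data$ani), mean_ani = mean(.data$ani),
                .groups = "drop") |>
      filter(ani_cmp(.data$best, ani_threshold))
    if (nrow(by_cluster) == 0) return(NULL)
    chosen <- by_cluster |>
      arrange(desc(.data$mean_ani), .data$cluster) |>
      dplyr::slice(1)
    tibble(genome_id = r, cluster = chosen$cluster)
  })
  recruit_tbl <- bind_rows(recruit_rows)  # empty tibble when none qualify
  assigned <- bind_rows(membership, recruit_tbl)

  # deterministic mOTU ids: decreasing size, then smallest member id
  cluster_order <- assigned |>
    group_by(.data$cluster) |>
    summarise(size = n(), first_member = min(.data$genome_id),
              .groups = "drop") |>
    arrange(desc(.data$size), .data$first_member)
  width <- max(2, nchar(nrow(cluster_order)))
  cluster_order$motu_id <- sprintf(paste0("mOTU%0", width, "d"),
                                   seq_len(nrow(cluster_order)))
  assigned <- assigned |>
    left_join(cluster_order |> select("cluster", "motu_id"), by = "cluster") |>
    select("genome_id", "motu_id")

  out <- meta |>
    left_join(assigned, by = "genome_id") |>
    mutate(
      tier = ifelse(.data$tier == "recruited" & is.na(.data$motu_id),
                    "excluded", .data$tier),
      reason = ifelse(.data$tier == "excluded" & is.na(.data$reason),
                      "unrecruited", .data$reason)
    ) |>
    select("genome_id", "motu_id", "tier", "reason",
           "completeness", "contamination")

  # representatives: most complete seed member, ties by min contamination
  # then lexicographic id
  reps <- out |>
    filter(.data$tier == "seed") |>
    group_by(.data$motu_id) |>
    arrange(desc(.data$completeness), .data$contamination, .data$genome_id,
            .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    pull(.data$genome_id)
  out <- out |>
    mutate(is_representative = .data$genome_id %in% reps) |>
    select("genome_id", "motu_id", "tier", "is_representative", "reason") |>
    arrange(is.na(.data$motu_id), .data$motu_id, desc(.data$tier == "seed"),
            .data$genome_id)

  structure(out,
            class = c("motu_catalog", class(tibble())),
            ani_threshold = ani_threshold, comp_seed_min = comp_seed_min,
            comp_recruit_min = comp_recruit_min, contam_max = contam_max)
}

#' Pick the representative genome of an mOTU
#'
#' The most complete seed-tier member; ties broken by minimum contamination,
#' then lexicographic genome id.
#'
#' @param members character vector of member genome ids.
#' @param genomes genome metadata tibble (genome_id, completeness,
#'   contamination, and optionally tier).
#' @return a single genome id.
#' @export
select_representative <- function(members, genomes) {
  stopifnot(length(members) > 0)
  cand <- genomes |> filter(.data$genome_id %in% members)
  if ("tier" %in% names(cand)) {
    seed <- cand |> filter(.data$tier == "seed")
    if (nrow(seed) == 0) {
      abort("mOTU has no seed-tier member; recruits cannot form an mOTU alone.")
    }
    cand <- seed
  }
  cand |>
    arrange(desc(.data$completeness), .data$contamination, .data$genome_id) |>
    dplyr::slice(1) |>
    pull(.data$genome_id)
}

#' @exportS3Method generics::tidy
tidy.motu_catalog <- function(x, ...) as_tibble(x)

#' @exportS3Method generics::glance
glance.motu_catalog <- function(x, ...) {
  tibble(
    n_genomes = nrow(x),
    n_motus = dplyr::n_distinct(x$motu_id[!is.na(x$motu_id)]),
    n_seed = sum(x$tier == "seed"),
    n_recruited = sum(x$tier == "recruited"),
    n_excluded = sum(x$tier == "excluded"),
    largest_motu = if (any(!is.na(x$motu_id))) {
      max(table(x$motu_id))
    } else 0L,
    ani_threshold = attr(x, "ani_threshold")
  )
}

#' Plot mOTU sizes by membership tier
#'
#' @param object a `motu_catalog` from [cluster_motus()].
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.motu_catalog <- function(object, ...) {
  df <- as_tibble(object) |> filter(!is.na(.data$motu_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$motu_id, fill = .data$tier)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "mOTU", y = "member genomes", fill = "tier") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
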