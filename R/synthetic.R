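# Synthetic-community generator: species pangenomes, degraded genomes,
# divergent sequences and metagenome read mixtures with known ground truth.

#' Specify a synthetic species pangenome
#'
#' Builds one row of a species table consumed by [generate_pangenome()],
#' [generate_sequences()] and [simulate_community()]. A species is a shared
#' core-gene set plus an accessory pool whose genes segregate independently
#' at a fixed frequency, with member genomes diverging from a common ancestor
#' at a controlled average nucleotide identity.
#'
#' @param species_id species label.
#' @param n_core_genes number of core gene clusters (>= 1).
#' @param n_accessory_pool size of the accessory gene pool (>= 0).
#' @param accessory_freq per-gene carriage frequency in (0, 1).
#' @param genome_length ancestral genome length in bases.
#' @param within_ani target within-species average nucleotide identity,
#'   percent in (90, 100].
#' @param n_genomes number of member genomes.
#' @return a one-row tibble; rows from several calls can be stacked with
#'   [dplyr::bind_rows()].
#' @examples
#' species_spec("sp1", n_core_genes = 100, n_accessory_pool = 50)
#' @export
species_spec <- function(species_id, n_core_genes = 1000,
                         n_accessory_pool = 1000, accessory_freq = 0.3,
                         genome_length = 100000, within_ani = 98,
                         n_genomes = 10) {
  spec <- tibble(
    species_id = as.character(species_id),
    n_core_genes = n_core_genes, n_accessory_pool = n_accessory_pool,
    accessory_freq = accessory_freq, genome_length = genome_length,
    within_ani = within_ani, n_genomes = n_genomes
  )
  validate_species_spec(spec)
  spec
}

validate_species_spec <- function(spec) {
  stopifnot(is.data.frame(spec))
  required <- c("species_id", "n_core_genes", "n_accessory_pool",
                "accessory_freq", "genome_length", "within_ani", "n_genomes")
  missing <- setdiff(required, names(spec))
  if (length(missing) > 0) {
    abort(paste0("species spec is missing fields: ",
                 paste(missing, collapse = ", ")))
  }
  for (i in seq_len(nrow(spec))) {
    row <- spec[i, ]
    assert_count(row$n_core_genes, "n_core_genes", min = 1)
    assert_count(row$n_accessory_pool, "n_accessory_pool", min = 0)
    if (row$n_accessory_pool > 0) {
      assert_scalar_prob(row$accessory_freq, "accessory_freq",
                         lower_open = TRUE, upper_open = TRUE)
    }
    assert_count(row$genome_length, "genome_length", min = 1)
    assert_count(row$n_genomes, "n_genomes", min = 1)
    if (!is.numeric(row$within_ani) || row$within_ani <= 90 ||
        row$within_ani > 100) {
      abort(sprintf("`within_ani` must be in (90, 100] (got %g).",
                    row$within_ani))
    }
  }
  invisible(spec)
}

#' Generate a species pangenome with planted core and accessory genes
#'
#' Every member genome receives all core genes; each accessory-pool gene is
#' carried by genome *i* independently with frequency `accessory_freq`
#' (optionally a per-gene vector recycled across the pool). Gene labels are
#' namespaced by species so multi-species gene catalogs never collide.
#'
#' @param spec a one-row species table from [species_spec()].
#' @param seed integer seed; output is reproducible bit-for-bit.
#' @return a list with elements
#'   * `genes`: tibble (gene, role, freq) — the species gene catalog,
#'   * `content`: tibble (genome_id, gene) — true gene content per genome.
#' @examples
#' pg <- generate_pangenome(species_spec("sp1", 10, 5, 0.5, n_genomes = 3), seed = 1)
#' dplyr::count(pg$content, genome_id)
#' @export
generate_pangenome <- function(spec, seed) {
  validate_species_spec(spec)
  stopifnot(nrow(spec) == 1)
  sp <- spec$species_id
  n_core <- as.integer(spec$n_core_genes)
  n_acc <- as.integer(spec$n_accessory_pool)
  n_gen <- as.integer(spec$n_genomes)
  freq <- spec$accessory_freq
  if (is.list(freq)) freq <- freq[[1]]
  if (n_acc > 0) {
    if (any(freq <= 0 | freq >= 1)) {
      abort("`accessory_freq` must be strictly inside (0, 1).")
    }
    freq <- rep_len(freq, n_acc)
  } else {
    freq <- numeric(0)
  }

  core_genes <- sprintf("%s_core_%04d", sp, seq_len(n_core))
  acc_genes <- if (n_acc > 0) sprintf("%s_acc_%04d", sp, seq_len(n_acc)) else character(0)
  genes <- tibble(
    gene = c(core_genes, acc_genes),
    role = rep(c("core", "accessory"), c(n_core, n_acc)),
    freq = c(rep(1, n_core), freq)
  )

  genome_ids <- sprintf("%s_g%02d", sp, seq_len(n_gen))
  content <- with_seed(seed, {
    purrr::map(genome_ids, function(g) {
      carried <- if (n_acc > 0) acc_genes[runif(n_acc) < freq] else character(0)
      tibble(genome_id = g, gene = c(core_genes, carried))
    })
  })
  list(genes = genes, content = bind_rows(content))
}

#' Degrade a genome's gene content by incompleteness and contamination
#'
#' Emulates what an incomplete, possibly contaminated draft genome (MAG/SAG)
#' observes of its true gene content: each true gene is retained
#' independently with probability `completeness`; each gene of the foreign
#' pool is added independently with probability `contamination_rate`.
#'
#' @param true_genes character vector of true gene labels.
#' @param completeness retention probability in (0, 1].
#' @param contamination_rate per-foreign-gene inclusion probability in [0, 1).
#' @param foreign_pool character vector of genes contamination may introduce.
#' @param seed integer seed.
#' @return character vector: the observed gene set.
#' @examples
#' degrade_genome(paste0("g", 1:10), completeness = 0.5, seed = 1)
#' @export
degrade_genome <- function(true_genes, completeness, contamination_rate = 0,
                           foreign_pool = character(0), seed = 1) {
  stopifnot(is.character(true_genes))
  assert_scalar_prob(completeness, "completeness", lower_open = TRUE)
  assert_scalar_prob(contamination_rate, "contamination_rate",
                     upper_open = TRUE)
  with_seed(seed, {
    kept <- true_genes[runif(length(true_genes)) < completeness]
    foreign <- foreign_pool[runif(length(foreign_pool)) < contamination_rate]
    unique(c(kept, foreign))
  })
}

#' Generate member-genome sequences at a controlled within-species ANI
#'
#' Draws one random ancestral sequence per species and derives each member
#' genome by independent substitutions at per-base rate
#' `(100 - within_ani) / 200`, so two members differ at roughly
#' `(100 - within_ani)%` of sites and their expected pairwise identity is the
#' requested `within_ani`. Ancestors of different species are independent, so
#' between-species identity is at the random-sequence background.
#'
#' @inheritParams generate_pangenome
#' @return named character vector of genome sequences
#'   (`<species>_g01`, ...); the ancestor is attached as attribute
#'   `"ancestor"`.
#' @examples
#' seqs <- generate_sequences(species_spec("sp1", genome_length = 500, n_genomes = 2), seed = 1)
#' nchar(seqs)
#' @export
generate_sequences <- function(spec, seed) {
  validate_species_spec(spec)
  stopifnot(nrow(spec) == 1)
  len <- as.integer(spec$genome_length)
  n_gen <- as.integer(spec$n_genomes)
  rate <- (100 - spec$within_ani) / 100 / 2
  genome_ids <- sprintf("%s_g%02d", spec$species_id, seq_len(n_gen))
  with_seed(seed, {
    ancestor_chars <- sample(DNA_BASES, len, replace = TRUE)
    seqs <- vapply(seq_len(n_gen), function(i) {
      chars <- ancestor_chars
      n_mut <- rbinom(1, len, rate)
      if (n_mut > 0) {
        pos <- sample.int(len, n_mut)
        # substitute to one of the three other bases, uniformly
        offset <- sample.int(3, n_mut, replace = TRUE)
        idx <- (match(chars[pos], DNA_BASES) - 1 + offset) %% 4 + 1
        chars[pos] <- DNA_BASES[idx]
      }
      paste(chars, collapse = "")
    }, character(1))
    structure(setNames(seqs, genome_ids),
              ancestor = paste(ancestor_chars, collapse = ""))
  })
}

# Random background sequence sharing no `k`-mers (either strand) with any
# genome, found by rejection sampling. At random this passes on the first try
# for k = 31; the loop guards pathological inputs.
background_sequence <- function(genomes, length_out, k = 31, max_tries = 20) {
  genome_kmers <- unique(unlist(lapply(genomes, function(s) {
    c(seq_windows(s, k), seq_windows(revcomp(s), k))
  }), use.names = FALSE))
  for (i in seq_len(max_tries)) {
    cand <- random_dna(length_out)
    if (!any(data.table::`%chin%`(seq_windows(cand, k), genome_kmers))) {
      return(cand)
    }
  }
  abort("could not draw a background sequence disjoint from the genomes")
}

#' Simulate a metagenome read set with planted genome abundances
#'
#' Draws single-end reads from a set of genome sequences in proportion to
#' planted per-genome relative abundances. The remainder (`1 - sum(abund)`)
#' comes from a random background sequence that shares no 31-mers with any
#' genome, so reads from it can never map back at 100% identity. Read
#' positions and strands are uniform; sequencing noise is independent
#' per-base substitution at `error_rate`.
#'
#' @param genomes named character vector of genome sequences.
#' @param abundances named numeric vector (genome_id -> relative abundance);
#'   must sum to <= 1.
#' @param n_reads number of reads to draw.
#' @param read_length read length in bases (<= shortest genome).
#' @param error_rate per-base substitution error rate in [0, 1).
#' @param seed integer seed.
#' @return tibble (read_id, sequence, source) where source is a genome id or
#'   `"background"`; the background sequence is attached as attribute
#'   `"background"`.
#' @examples
#' g <- setNames(paste(sample(c("A","C","G","T"), 400, TRUE), collapse = ""), "gA")
#' reads <- generate_reads(g, c(gA = 1), n_reads = 5, read_length = 50, seed = 1)
#' @export
generate_reads <- function(genomes, abundances, n_reads = 10000,
                           read_length = 150, error_rate = 0, seed = 1) {
  stopifnot(is.character(genomes), !is.null(names(genomes)))
  assert_count(n_reads, "n_reads", min = 1)
  assert_count(read_length, "read_length", min = 1)
  assert_scalar_prob(error_rate, "error_rate", upper_open = TRUE)
  if (!all(names(abundances) %in% names(genomes))) {
    abort("abundances refer to genomes not present in `genomes`.")
  }
  if (any(abundances < 0) || sum(abundances) > 1 + 1e-9) {
    abort("planted abundances must be >= 0 and sum to <= 1.")
  }
  if (read_length > min(nchar(genomes))) {
    abort("`read_length` exceeds the shortest genome.")
  }

  with_seed(seed, {
    bg_frac <- max(0, 1 - sum(abundances))
    background <- if (bg_frac > 0) {
      # drawn under a derived child seed: a caller may have generated the
      # genomes themselves under `seed`, and reusing that stream here would
      # replay the genome bases into the background candidate
      with_seed(child_seed(seed, 104729L),
                background_sequence(genomes, max(read_length * 20, 2000)))
    } else {
      NA_character_
    }
    sources <- c(names(abundances), "background")
    probs <- c(unname(abundances), bg_frac)
    draw <- sample(sources, n_reads, replace = TRUE, prob = probs)
    pool <- c(genomes, background = background)
    tmpl <- unname(pool[draw])
    start <- 1L + floor(runif(n_reads) * (nchar(tmpl) - read_length + 1))
    reads <- substring(tmpl, start, start + read_length - 1)
    flip <- runif(n_reads) < 0.5
    if (any(flip)) reads[flip] <- revcomp(reads[flip])
    if (error_rate > 0) {
      n_err <- rbinom(n_reads, read_length, error_rate)
      for (i in which(n_err > 0)) {
        chars <- strsplit(reads[i], "", fixed = TRUE)[[1]]
        pos <- sample.int(read_length, n_err[i])
        offset <- sample.int(3, n_err[i], replace = TRUE)
        chars[pos] <- DNA_BASES[(match(chars[pos], DNA_BASES) - 1 + offset) %% 4 + 1]
        reads[i] <- paste(chars, collapse = "")
      }
    }
    structure(
      tibble(read_id = sprintf("read_%06d", seq_len(n_reads)),
             sequence = reads, source = unname(draw)),
      background = background
    )
  })
}

#' Simulate a complete multi-site synthetic community with ground truth
#'
#' End-to-end generator tying the pieces together: species pangenomes and
#' sequences, genome degradation to MAG-like quality, genome-to-site
#' assignment, and per-sample metagenome read sets with planted mOTU
#' abundances across a site -> region -> country -> continent hierarchy.
#' Every downstream stage of the pipeline can be tested against the returned
#' truth tables.
#'
#' @param species species table (rows from [species_spec()]).
#' @param sites tibble (site_id, region, country, continent, n_samples).
#' @param abundances tibble (site_id, species_id, abundance): planted
#'   relative abundance of each species in every sample of the site; a
#'   species' abundance is split equally across its member genomes. Per-site
#'   totals must be <= 1 (remainder = unmapped background).
#' @param completeness per-genome completeness: single value or named vector
#'   over genome ids, fractions in (0, 1].
#' @param contamination_rate per-genome contamination rate (fraction).
#' @param n_reads reads per sample.
#' @param read_length read length (bases).
#' @param error_rate per-base read error rate.
#' @param genome_sites optional tibble (genome_id, site_id) fixing genome
#'   provenance; by default genomes of a species cycle through the sites
#'   where the species is planted (or the first site if it is planted
#'   nowhere).
#' @param seed integer master seed; all stages derive child seeds from it.
#' @return a list with elements `genomes` (metadata tibble: genome_id,
#'   species_id, completeness, contamination, site, region, country,
#'   continent, kind), `sequences` (named character vector), `gene_content`
#'   (observed, long tibble), `presence` (observed wide 0/1 tibble),
#'   `samples` (sample metadata tibble), `reads` (named list of read
#'   tibbles, one per sample), and `truth` (list: gene_content, core_sets,
#'   partition, abundances).
#' @examples
#' sp <- species_spec("sp1", 50, 20, 0.5, genome_length = 2000, n_genomes = 3)
#' st <- tibble::tibble(site_id = "L1", region = "R1", country = "C1",
#'                      continent = "Europe", n_samples = 1)
#' ab <- tibble::tibble(site_id = "L1", species_id = "sp1", abundance = 0.5)
#' sim <- simulate_community(sp, st, ab, n_reads = 100, seed = 1)
#' @export
simulate_community <- function(species, sites, abundances,
                               completeness = 0.95, contamination_rate = 0,
                               n_reads = 10000, read_length = 150,
                               error_rate = 0, genome_sites = NULL,
                               seed = 1) {
  validate_species_spec(species)
  stopifnot(all(c("site_id", "region", "country", "continent", "n_samples")
                %in% names(sites)))
  stopifnot(all(c("site_id", "species_id", "abundance") %in% names(abundances)))
  bad_sites <- abundances |>
    group_by(.data$site_id) |>
    summarise(total = sum(.data$abundance), .groups = "drop") |>
    filter(.data$total > 1 + 1e-9)
  if (nrow(bad_sites) > 0) {
    abort(paste0("planted abundances exceed 1 at site(s): ",
                 paste(bad_sites$site_id, collapse = ", ")))
  }

  # per-species generation
  pangenomes <- list(); sequences <- character(0); true_content <- list()
  for (i in seq_len(nrow(species))) {
    row <- species[i, ]
    pg <- generate_pangenome(row, seed = child_seed(seed, i))
    sq <- generate_sequences(row, seed = child_seed(seed, 1000 + i))
    pangenomes[[row$species_id]] <- pg
    sequences <- c(sequences, sq)
    true_content[[row$species_id]] <- pg$content
  }
  true_content <- bind_rows(true_content)

  genome_ids <- names(sequences)
  partition <- tibble(
    genome_id = genome_ids,
    species_id = sub("_g[0-9]+$", "", genome_ids)
  )

  comp <- completeness_vector(completeness, genome_ids)

  # site assignment: cycle each species' genomes through its planted sites
  if (is.null(genome_sites)) {
    genome_sites <- partition |>
      group_by(.data$species_id) |>
      mutate(site_id = {
        planted <- sort(unique(
          abundances$site_id[abundances$species_id == .data$species_id[1] &
                             abundances$abundance > 0]))
        if (length(planted) == 0) planted <- sites$site_id[1]
        rep_len(planted, n())
      }) |>
      ungroup() |>
      select("genome_id", "site_id")
  }
  genomes_meta <- partition |>
    left_join(genome_sites, by = "genome_id") |>
    left_join(sites |> select("site_id", "region", "country", "continent"),
              by = "site_id") |>
    mutate(completeness = unname(comp[.data$genome_id]) * 100,
           contamination = contamination_rate * 100,
           kind = "MAG") |>
    rename(site = "site_id")

  # observed (degraded) gene content
  all_genes_by_sp <- lapply(pangenomes, function(pg) pg$genes$gene)
  observed <- purrr::imap(split(true_content$gene, true_content$genome_id),
    function(genes, g) {
      sp <- partition$species_id[match(g, partition$genome_id)]
      foreign <- unlist(all_genes_by_sp[setdiff(names(all_genes_by_sp), sp)],
                        use.names = FALSE)
      tibble(genome_id = g,
             gene = degrade_genome(genes, comp[[g]], contamination_rate,
                                   foreign,
                                   seed = child_seed(seed, 2000 + match(g, genome_ids))))
    })
  gene_content <- bind_rows(observed)

  # samples and reads
  samples <- sites |>
    tidyr::uncount(.data$n_samples, .id = "rep") |>
    mutate(sample_id = sprintf("%s_s%02d", .data$site_id, .data$rep)) |>
    select("sample_id", "site_id", "region", "country", "continent")

  members <- split(partition$genome_id, partition$species_id)
  reads <- purrr::map(seq_len(nrow(samples)), function(j) {
    site <- samples$site_id[j]
    ab <- abundances |> filter(.data$site_id == site, .data$abundance > 0)
    genome_ab <- numeric(0)
    for (r in seq_len(nrow(ab))) {
      mg <- members[[ab$species_id[r]]]
      genome_ab <- c(genome_ab,
                     setNames(rep(ab$abundance[r] / length(mg), length(mg)), mg))
    }
    generate_reads(sequences, genome_ab, n_reads = n_reads,
                   read_length = read_length, error_rate = error_rate,
                   seed = child_seed(seed, 3000 + j))
  })
  names(reads) <- samples$sample_id

  true_core <- bind_rows(purrr::imap(pangenomes, function(pg, sp) {
    tibble(species_id = sp, gene = pg$genes$gene[pg$genes$role == "core"])
  }))
  true_abund <- samples |>
    select("sample_id", "site_id") |>
    inner_join(abundances, by = "site_id",
               relationship = "many-to-many") |>
    select("sample_id", "species_id", "abundance")

  list(
    genomes = genomes_meta,
    sequences = sequences,
    gene_content = gene_content,
    presence = presence_matrix(gene_content),
    samples = samples,
    reads = reads,
    truth = list(gene_content = true_content, core_sets = true_core,
                 partition = partition, abundances = true_abund)
  )
}

#' Pivot long gene content to a wide 0/1 presence matrix
#'
#' @param content tibble (genome_id, gene).
#' @param genomes optional character vector of genome ids to include as
#'   columns (all-absent genomes get zero columns).
#' @return tibble with a `gene` column and one 0/1 integer column per genome.
#' @export
presence_matrix <- function(content, genomes = NULL) {
  stopifnot(all(c("genome_id", "gene") %in% names(content)))
  genomes <- genomes %||% sort(unique(content$genome_id))
  wide <- content |>
    filter(.data$genome_id %in% genomes) |>
    distinct(.data$gene, .data$genome_id) |>
    mutate(present = 1L) |>
    tidyr::pivot_wider(names_from = "genome_id", values_from = "present",
                       values_fill = 0L) |>
    arrange(.data$gene)
  for (g in setdiff(genomes, names(wide))) wide[[g]] <- 0L
  wide[, c("gene", genomes)]
}
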