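# Shared fixtures, built in code at test time.

# Two-species community on two continents, small genomes, used by several
# module tests. Species spA is planted at both sites (two continents),
# spB only at L1.
tiny_community <- function(seed = 11, n_reads = 2000, completeness = 0.9,
                           error_rate = 0) {
  sp <- dplyr::bind_rows(
    species_spec("spA", n_core_genes = 60, n_accessory_pool = 40,
                 accessory_freq = 0.3, genome_length = 5000,
                 within_ani = 98, n_genomes = 4),
    species_spec("spB", n_core_genes = 60, n_accessory_pool = 40,
                 accessory_freq = 0.3, genome_length = 5000,
                 within_ani = 98, n_genomes = 4)
  )
  st <- tibble::tibble(
    site_id = c("L1", "L2"), region = c("Scandinavia", "Ontario"),
    country = c("Sweden", "Canada"),
    continent = c("Europe", "North America"), n_samples = c(2, 1)
  )
  ab <- tibble::tibble(
    site_id = c("L1", "L1", "L2"), species_id = c("spA", "spB", "spA"),
    abundance = c(0.3, 0.2, 0.4)
  )
  simulate_community(sp, st, ab, completeness = completeness,
                     n_reads = n_reads, error_rate = error_rate, seed = seed)
}

# independent clustering oracle: exhaustive union-find over all
# above-threshold pairs
union_find_components <- function(ids, ani, threshold) {
  parent <- setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (r in seq_len(nrow(ani))) {
    if (ani$ani[r] > threshold &&
        ani$query[r] %in% ids && ani$reference[r] %in% ids) {
      ra <- find(ani$query[r]); rb <- find(ani$reference[r])
      if (ra != rb) parent[[ra]] <- rb
    }
  }
  vapply(ids, find, character(1))
}

# planted-vs-recovered partition agreement (independent of label names)
expect_same_partition <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b))
  expect_equal(
    outer(labels_a, labels_a, "=="),
    outer(labels_b, labels_b, "=="),
    ignore_attr = TRUE
  )
}

# F1 of recovering planted core genes, truth taken from gene labels
core_f1 <- function(fit) {
  td <- tidy(fit)
  truth <- ifelse(grepl("_core_", td$gene), "core", "accessory")
  tp <- sum(td$assignment == "core" & truth == "core")
  if (tp == 0) return(0)
  prec <- tp / sum(td$assignment == "core")
  rec <- tp / sum(truth == "core")
  2 * prec * rec / (prec + rec)
}

# observed gene content for one species after uniform degradation
degraded_presence <- function(spec, completeness, seed) {
  pg <- generate_pangenome(spec, seed)
  by_genome <- split(pg$content$gene, pg$content$genome_id)
  obs <- purrr::map2(by_genome, seq_along(by_genome), function(genes, i) {
    tibble::tibble(
      genome_id = names(by_genome)[i],
      gene = degrade_genome(genes, completeness, seed = seed + 37 * i)
    )
  })
  presence_matrix(dplyr::bind_rows(obs))
}

hamming_identity <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  100 * mean(ca == cb)
}
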