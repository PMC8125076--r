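# Marker filtering, trait status and biogeography classification.

test_that("hit filtering applies inclusive coverage and per-marker identity thresholds", {
  hits <- tibble::tibble(
    genome_id = c("g1", "g1", "g2", "g2", "g3"),
    marker = c("Sqr", "PsaA", "PsaA", "DsrA", "Sqr"),
    identity = c(50.0, 79.9, 80.0, 49.9, 95),
    coverage = c(80.0, 95, 85, 99, 79.9)
  )
  out <- filter_hits(hits)
  # boundary-inclusive Sqr hit passes (identity 50, coverage 80)
  expect_true(nrow(dplyr::filter(out, genome_id == "g1", marker == "Sqr")) == 1)
  # PsaA requires 80% identity: 79.9 fails, 80.0 passes
  expect_false(any(out$genome_id == "g1" & out$marker == "PsaA"))
  expect_true(any(out$genome_id == "g2" & out$marker == "PsaA"))
  # identity below the default bar fails; coverage below 80 fails
  expect_false(any(out$marker == "DsrA"))
  expect_false(any(out$genome_id == "g3"))
  # empty table -> nothing present
  expect_equal(nrow(filter_hits(hits[0, ])), 0)
  # a marker with no threshold available is an error naming it
  expect_error(filter_hits(hits, identity_default = NA), "Sqr")
})

test_that("hit tables load from both the 4-column and 12-column dialects", {
  dir <- withr::local_tempdir()
  p4 <- file.path(dir, "hits4.tsv")
  writeLines(c("genome_id\tmarker\tidentity\tcoverage",
               "g1\tSqr\t60\t90"), p4)
  t4 <- read_hit_table(p4)
  expect_equal(t4$marker, "Sqr")
  p12 <- file.path(dir, "hits12.tsv")
  writeLines(paste(c("g1", "Sqr", "61.5", "90", "3", "0", "11", "100",
                     "1", "90", "1e-30", "200"), collapse = "\t"), p12)
  qlen <- tibble::tibble(query_id = "g1", length = 100)
  t12 <- read_hit_table(p12, query_lengths = qlen)
  expect_equal(t12$identity, 61.5)
  expect_equal(t12$coverage, 90) # (100 - 11 + 1) / 100
  expect_error(read_hit_table(p12), "query_lengths")
})

test_that("trait status is absent only when no member carries the marker, else follows the likelihood rule", {
  sim <- tiny_community(seed = 51, n_reads = 100, completeness = 0.9)
  cat <- cluster_motus(pairwise_ani(sim$sequences, k = 21), sim$genomes)
  members <- tibble::as_tibble(cat) |> dplyr::filter(!is.na(motu_id))
  mA <- members$motu_id[match("spA_g01", members$genome_id)]
  ids_A <- members$genome_id[members$motu_id == mA]

  marker_presence <- dplyr::bind_rows(
    tibble::tibble(genome_id = ids_A, marker = "PsaA"),       # in all -> core
    tibble::tibble(genome_id = ids_A[1], marker = "NifH")     # in 1 -> accessory-ish
  )
  traits <- suppressWarnings(
    motu_traits(marker_presence, cat, sim$gene_content, sim$genomes,
                markers = c("PsaA", "NifH", "DsrA")))
  rowA <- function(mk) traits[traits$motu_id == mA & traits$marker == mk, ]
  expect_equal(rowA("PsaA")$status, "core")
  expect_equal(rowA("DsrA")$status, "absent") # never seen in any member
  expect_true(is.na(rowA("DsrA")$loglik_core))
  # status != absent reproduces the decision rule from the log-likelihoods
  filled <- traits[traits$status != "absent", ]
  expect_equal(filled$status,
               ifelse(filled$loglik_core > filled$loglik_accessory,
                      "core", "accessory"))
  # the other mOTU never saw these markers at all
  other <- traits[traits$motu_id != mA, ]
  expect_true(all(other$status == "absent"))
  expect_s3_class(autoplot(traits), "ggplot")
})

test_that("a marker in one of ten members at carriage 0.3 is accessory by the worked comparison", {
  # presence context engineered so accessory carriage ~ 0.3 per genome
  set.seed(6)
  ids <- sprintf("g%02d", 1:10)
  acc <- purrr::map(ids, function(g) {
    tibble::tibble(genome_id = g,
                   gene = c(sprintf("sp_core_%03d", 1:100),
                            sprintf("sp_acc_%03d",
                                    which(runif(100) < 0.3))))
  }) |> dplyr::bind_rows()
  ani <- tidyr::expand_grid(query = ids, reference = ids) |>
    dplyr::filter(query < reference) |>
    dplyr::mutate(ani = 98)
  meta <- tibble::tibble(genome_id = ids, completeness = 90,
                         contamination = 0)
  cat <- cluster_motus(ani, meta)
  mp <- tibble::tibble(genome_id = ids[1], marker = "HyaB")
  traits <- suppressWarnings(
    motu_traits(mp, cat, acc, setNames(rep(0.9, 10), ids)))
  expect_equal(traits$status, "accessory")
  expect_lt(traits$loglik_core, traits$loglik_accessory)
  # LLcore ~ ln(0.9) + 9 ln(0.1) = -20.83 at completeness 0.9
  expect_equal(round(traits$loglik_core, 2), -20.83)
})

test_that("biogeography classification follows the continent/region/site rule table", {
  cat <- structure(
    tibble::tibble(
      genome_id = c("a1", "a2", "b1", "c1", "c2"),
      motu_id = c("m1", "m1", "m2", "m3", "m3"),
      tier = "seed", is_representative = c(TRUE, FALSE, TRUE, TRUE, FALSE),
      reason = NA_character_
    ), class = c("motu_catalog", class(tibble::tibble())))
  genomes <- tibble::tibble(
    genome_id = c("a1", "a2", "b1", "c1", "c2"),
    site = c("LSwe", "LCan", "LFin", "LNor1", "LNor2"),
    region = c("Scandinavia", "Ontario", "Scandinavia", "Norrland", "Norrland"),
    country = c("Sweden", "Canada", "Finland", "Sweden", "Sweden"),
    continent = c("Europe", "North America", "Europe", "Europe", "Europe")
  )
  bio <- classify_biogeography(cat, genomes)
  expect_equal(bio$classification[bio$motu_id == "m1"], "cosmopolitan")
  expect_equal(bio$classification[bio$motu_id == "m2"], "endemic")  # one lake
  expect_equal(bio$classification[bio$motu_id == "m3"], "endemic")  # one region, two sites

  # occupancy adding a second region on the same continent -> regional
  sites <- tibble::tibble(
    site_id = "LUpp", region = "Svealand", country = "Sweden",
    continent = "Europe"
  )
  occ <- tibble::tibble(motu_id = "m3", site_id = "LUpp",
                        mean_abundance = 0.01, present = TRUE)
  bio2 <- classify_biogeography(cat, genomes, occ, sites)
  expect_equal(bio2$classification[bio2$motu_id == "m3"], "regional")
  # evidence channels are reported separately
  expect_equal(bio2$continents_reads[bio2$motu_id == "m3"], "Europe")
  # occupancy evidence never demotes a cosmopolitan mOTU
  occ_extra <- tibble::tibble(motu_id = "m1", site_id = "LUpp",
                              mean_abundance = 0.01, present = TRUE)
  bio3 <- classify_biogeography(cat, genomes, occ_extra, sites)
  expect_equal(bio3$classification[bio3$motu_id == "m1"], "cosmopolitan")
  # an mOTU with no located evidence is flagged unknown
  cat_u <- structure(
    tibble::tibble(genome_id = "z1", motu_id = "m9", tier = "seed",
                   is_representative = TRUE, reason = NA_character_),
    class = c("motu_catalog", class(tibble::tibble())))
  genomes_u <- tibble::tibble(genome_id = "z1", site = NA_character_,
                              region = NA, country = NA, continent = NA)
  expect_equal(classify_biogeography(cat_u, genomes_u)$classification,
               "unknown")
})

test_that("planted markers recover their trait status end to end", {
  sim <- tiny_community(seed = 57, n_reads = 100, completeness = 0.999)
  cat <- cluster_motus(pairwise_ani(sim$sequences, k = 21), sim$genomes)
  members <- tibble::as_tibble(cat) |> dplyr::filter(!is.na(motu_id))
  # plant: marker in every genome of each mOTU -> core; never planted -> absent
  mp <- tibble::tibble(genome_id = members$genome_id, marker = "SoxB")
  traits <- motu_traits(mp, cat, sim$gene_content, sim$genomes,
                        markers = c("SoxB", "AclB"))
  expect_true(all(traits$status[traits$marker == "SoxB"] == "core"))
  expect_true(all(traits$status[traits$marker == "AclB"] == "absent"))
})
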