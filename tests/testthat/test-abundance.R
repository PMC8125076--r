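# Subsampling, exact-match competitive assignment, normalization,
# location averaging and the presence cutoff.

test_that("subsampling honours the target size, determinism and the undersize warning", {
  reads <- tibble::tibble(read_id = sprintf("r%04d", 1:2000),
                          sequence = strrep("A", 10))
  sub <- subsample_reads(reads, target = 1000, seed = 1)
  expect_equal(nrow(sub), 1000)
  expect_false(anyDuplicated(sub$read_id) > 0)
  expect_identical(sub, subsample_reads(reads, target = 1000, seed = 1))
  expect_warning(out <- subsample_reads(reads[1:500, ], target = 1e6),
                 "below")
  expect_equal(nrow(out), 500)
  expect_error(subsample_reads(reads[0, ], target = 10), "empty")
})

test_that("the exact-match index enforces 100% identity on both strands", {
  set.seed(42)
  gA <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  gB <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  idx <- build_match_index(c(A = gA, B = gB), read_length = 60)
  verbatim <- substr(gA, 101, 160)
  expect_equal(match_reads(idx, verbatim)[[1]], "A")
  # reverse complement matches the same genome
  expect_equal(match_reads(idx, revcomp(verbatim))[[1]], "A")
  # one substitution breaks the match entirely
  mut <- verbatim
  substr(mut, 30, 30) <- setdiff(c("A", "C", "G", "T"),
                                 substr(mut, 30, 30))[1]
  expect_length(match_reads(idx, mut)[[1]], 0)
  # a read present in both genomes reports both
  shared <- substr(gA, 1, 60)
  gB2 <- paste0(shared, substr(gB, 61, 2000))
  idx2 <- build_match_index(c(A = gA, B = gB2), read_length = 60)
  expect_setequal(match_reads(idx2, shared)[[1]], c("A", "B"))
  # wrong read length is rejected; short genomes warn
  expect_error(match_reads(idx, "ACGT"), "length")
  expect_warning(build_match_index(c(S = "ACGTACGTACGTACGTACGTACGTACGTACGT"),
                                   read_length = 60), "shorter")
})

test_that("competitive assignment splits cross-mOTU reads and conserves counts", {
  map <- c(A1 = "mOTU_A", A2 = "mOTU_A", B1 = "mOTU_B")
  matches <- list(c("A1", "A2"),      # within-mOTU multi-match -> 1 to A
                  c("A1", "B1"),      # cross-mOTU -> 0.5 each
                  character(0),       # unmapped
                  "B1")
  counts <- competitive_assign(matches, map)
  expect_equal(counts$count[counts$motu_id == "mOTU_A"], 1.5)
  expect_equal(counts$count[counts$motu_id == "mOTU_B"], 1.5)
  expect_equal(counts$count[counts$motu_id == "unmapped"], 1)
  expect_equal(sum(counts$count), length(matches)) # conservation
  # discard policy tallies ambiguous reads separately, still conserving
  d <- competitive_assign(matches, map, ambiguous = "discard")
  expect_equal(sum(d$count), length(matches))
  expect_equal(d$count[d$motu_id == "discarded"], 1)
  # random policy is seeded and conserves
  r1 <- competitive_assign(matches, map, ambiguous = "random", seed = 4)
  r2 <- competitive_assign(matches, map, ambiguous = "random", seed = 4)
  expect_identical(r1, r2)
  expect_equal(sum(r1$count), length(matches))
  # a matched genome without an mOTU is an invariant error
  expect_error(competitive_assign(list("Z"), map), "without an mOTU")
})

test_that("relative abundance normalizes by the subsample size", {
  counts <- tibble::tibble(motu_id = c("m1", "m2"), count = c(300, 700))
  ab <- relative_abundance(counts, 1000)
  expect_equal(ab$abundance, c(0.3, 0.7))
  expect_equal(sum(ab$abundance), 1)
  big <- tibble::tibble(motu_id = "m1", count = 570000)
  expect_equal(relative_abundance(big, 1e6)$abundance, 0.57)
  expect_equal(relative_abundance(tibble::tibble(motu_id = "m1", count = 0),
                                  100)$abundance, 0)
  expect_error(relative_abundance(big, 1000), "exceed")
})

test_that("per-sample abundances plus unmapped sum to one exactly and recover planted values", {
  sim <- tiny_community(seed = 41, n_reads = 4000)
  cat <- cluster_motus(pairwise_ani(sim$sequences, k = 21), sim$genomes)
  am <- profile_abundance(sim$reads, sim$sequences, cat, subsample = 4000)
  totals <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(am), sample_id),
                             s = sum(abundance))
  expect_equal(totals$s, rep(1, nrow(totals)))

  # error-free reads: the estimate must equal the realized fraction of
  # reads drawn from each species exactly (all map, none cross mOTUs)
  motu_of_species <- tibble::as_tibble(cat) |>
    dplyr::filter(!is.na(motu_id)) |>
    dplyr::mutate(species_id = sub("_g.*", "", genome_id)) |>
    dplyr::distinct(species_id, motu_id)
  realized <- purrr::imap(sim$reads, function(rd, sid) {
    tibble::tibble(sample_id = sid,
                   species_id = sub("_g.*", "", rd$source)) |>
      dplyr::count(sample_id, species_id) |>
      dplyr::mutate(realized = n / nrow(rd))
  }) |> dplyr::bind_rows() |>
    dplyr::filter(species_id != "background")
  joined <- tibble::as_tibble(am) |>
    dplyr::inner_join(motu_of_species, by = "motu_id") |>
    dplyr::inner_join(realized, by = c("sample_id", "species_id"))
  expect_equal(joined$abundance, joined$realized)
  # and the realized fractions are themselves binomial draws around the
  # planted values (gross-error guard at 5 sigma)
  truth <- sim$truth$abundances
  j2 <- joined |> dplyr::inner_join(truth, by = c("sample_id", "species_id"))
  expect_true(all(abs(j2$abundance.x - j2$abundance.y) <
                    5 * sqrt(0.4 * 0.6 / 4000)))
})

test_that("reverse-complementing every read leaves all counts unchanged", {
  sim <- tiny_community(seed = 43, n_reads = 500)
  cat <- cluster_motus(pairwise_ani(sim$sequences, k = 21), sim$genomes)
  idx <- build_match_index(sim$sequences, read_length = 150)
  reads <- sim$reads[[1]]$sequence
  c1 <- competitive_assign(match_reads(idx, reads), cat)
  c2 <- competitive_assign(match_reads(idx, revcomp(reads)), cat)
  expect_equal(c1, c2)
})

test_that("location averaging is an unweighted mean including zeros", {
  ab <- tibble::tibble(
    sample_id = c("s1", "s2", "s3", "s1"),
    motu_id = c("m1", "m1", "m1", "unmapped"),
    abundance = c(0.10, 0.20, 0.00, 0.9)
  )
  samples <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                            site_id = c("L1", "L1", "L1"))
  occ <- aggregate_by_location(ab, samples)
  expect_equal(occ$mean_abundance, 0.10)
  expect_equal(occ$n_samples, 3)
  # a missing (mOTU, sample) pair averages in as zero
  ab2 <- ab[ab$sample_id != "s3", ]
  samples3 <- samples
  occ2 <- aggregate_by_location(ab2, samples3[1:2, ])
  expect_equal(occ2$mean_abundance, 0.15)
  # single-sample site equals that sample
  occ3 <- aggregate_by_location(ab[1, ], samples[1, ])
  expect_equal(occ3$mean_abundance, 0.10)
  # samples without metadata are an error listing ids
  expect_error(aggregate_by_location(ab, samples[1, ]), "s2")
})

test_that("the presence cutoff is inclusive and monotone", {
  occ <- tibble::tibble(
    motu_id = c("m1", "m2", "m3"), site_id = "L1",
    mean_abundance = c(0.0002, 0.0003, 0.57), n_samples = 2
  )
  flagged <- apply_presence_cutoff(occ, cutoff = 0.0003)
  expect_equal(flagged$present, c(FALSE, TRUE, TRUE))
  # monotonicity on a random matrix: raising the cutoff never adds presences
  set.seed(12)
  rnd <- tibble::tibble(
    motu_id = rep(sprintf("m%02d", 1:10), each = 4),
    site_id = rep(sprintf("L%d", 1:4), 10),
    mean_abundance = runif(40, 0, 0.002)
  )
  n_present <- vapply(c(1e-4, 3e-4, 6e-4, 1e-3),
                      function(ct) sum(apply_presence_cutoff(rnd, ct)$present),
                      numeric(1))
  expect_true(all(diff(n_present) <= 0))
})

test_that("read sets round-trip through FASTQ and genomes through FASTA", {
  sim <- tiny_community(seed = 47, n_reads = 50)
  dir <- withr::local_tempdir()
  fq <- file.path(dir, "s1.fastq")
  write_fastq(sim$reads[[1]], fq)
  back <- read_fastq(fq)
  expect_equal(back$sequence, sim$reads[[1]]$sequence)
  paths <- write_genomes(sim$sequences, dir = file.path(dir, "genomes"))
  g <- read_genomes(file.path(dir, "genomes"))
  expect_equal(g[order(names(g))],
               sim$sequences[order(names(sim$sequences))])
})
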