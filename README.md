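# motukit

Genome-resolved mOTU analysis at desk scale: species-level clustering of
metagenome-assembled genomes (MAGs) and single-amplified genomes (SAGs),
incompleteness-aware core/accessory pangenome partitioning, competitive
read-mapping abundance profiles, marker-gene trait matrices, and
cosmopolitan/regional/endemic biogeography — with a synthetic-community
generator so every stage can be tested against known ground truth.

## Who this is for

Microbial ecologists working with collections of draft genomes recovered
from environmental metagenomes. Draft genomes are incomplete (a genome at
80% completeness is *expected* to be missing a fifth of its genes), so
naive per-genome analyses conflate "gene absent from the population" with
"gene missed by assembly/binning". motukit implements an inference chain
that treats incompleteness as a first-class nuisance parameter.

## The methods in brief

**mOTU clustering.** Pairwise average nucleotide identity (ANI) is
estimated from canonical k-mer sets via the MinHash distance transform
`D = -(1/k) ln(2J/(1+J))`, `ANI = 100(1-D)` with Jaccard similarity `J`
(or imported from an external five-column ANI TSV). Genomes with
completeness ≥ 70% and contamination ≤ 5% form a graph with edges at
ANI > 95%; connected components are the mOTUs. Genomes at 50–70%
completeness are recruited into an mOTU when their ANI to a seed member
exceeds the threshold; everything else is retained as `excluded` with a
reason code. The most complete seed member represents each mOTU.

**Core/accessory partitioning.** For a gene with presence profile
`x_i ∈ {0,1}` over an mOTU's members with completeness `c_i`, the core
model scores `Σ_present ln c_i + Σ_absent ln(1-c_i)` (absences explained
by incompleteness) against an accessory model
`Σ_present ln p_i + Σ_absent ln(1-p_i)`, where `p_i` is genome *i*'s
observed accessory-gene carriage over the mOTU's accessory pool. The
assignment is iterated to a fixed point. A gene observed in *no* member is
never classified — it is reported `absent`, the evidence standard for a
gene missing from the population.

**Abundance and occupancy.** Each metagenome is subsampled to a fixed read
count (default 1,000,000), reads are matched at 100% identity (exact
full-length match, either strand) competitively against all catalog
genomes, counts are normalized to relative abundance per metagenome,
averaged per site, and a presence cutoff of 0.03% (0.0003) is applied.

**Traits and biogeography.** Marker-gene hit tables are filtered at 80%
query coverage and 50% identity (80% for PsaA), marker status per mOTU is
`core`/`accessory`/`absent` by the same likelihood rule, and each mOTU is
classified `cosmopolitan` (evidence on ≥ 2 continents), `endemic`
(confined to one site or one region) or `regional`, combining member-genome
origins with read-mapping occupancy.

## Worked example

```r
library(motukit)
library(dplyr)

# a two-species community across two continents, with ground truth
sp <- bind_rows(
  species_spec("spA", n_core_genes = 60, n_accessory_pool = 40,
               accessory_freq = 0.3, genome_length = 5000,
               within_ani = 98, n_genomes = 4),
  species_spec("spB", n_core_genes = 60, n_accessory_pool = 40,
               accessory_freq = 0.3, genome_length = 5000,
               within_ani = 98, n_genomes = 4))
st <- tibble(site_id = c("L1", "L2"), region = c("Scandinavia", "Ontario"),
             country = c("Sweden", "Canada"),
             continent = c("Europe", "North America"), n_samples = c(2, 1))
ab <- tibble(site_id = c("L1", "L1", "L2"),
             species_id = c("spA", "spB", "spA"),
             abundance = c(0.3, 0.2, 0.4))
sim <- simulate_community(sp, st, ab, completeness = 0.9,
                          n_reads = 2000, seed = 7)

catalog <- cluster_motus(pairwise_ani(sim$sequences, k = 21), sim$genomes)
glance(catalog)
#> # A tibble: 1 × 7
#>   n_genomes n_motus n_seed n_recruited n_excluded largest_motu ani_threshold
#> 1         8       2      8           0          0            4            95

fits <- classify_by_motu(sim$gene_content, catalog, sim$genomes)
summarize_partition(fits)
#> # A tibble: 2 × 7
#>   motu_id n_genes n_core n_accessory n_iterations converged ...
#> 1 mOTU01       87     43          44            2 TRUE
#> 2 mOTU02       88     49          39            2 TRUE

am <- profile_abundance(sim$reads, sim$sequences, catalog, subsample = 2000)
occupancy <- am |> aggregate_by_location(sim$samples) |> apply_presence_cutoff()
occupancy
#> # A tibble: 4 × 6
#>   motu_id site_id mean_abundance n_samples present
#> 1 mOTU01  L1               0.296         2 TRUE
#> 2 mOTU01  L2               0.413         1 TRUE
#> 3 mOTU02  L1               0.198         2 TRUE
#> 4 mOTU02  L2               0             1 FALSE

classify_biogeography(catalog, sim$genomes, occupancy, sites = st) |>
  select(motu_id, classification, continents)
#> # A tibble: 2 × 3
#>   motu_id classification continents
#> 1 mOTU01  cosmopolitan   Europe,North America
#> 2 mOTU02  endemic        Europe
```

The clustering recovers the two planted species exactly; the estimated
site-mean abundances (0.296, 0.413, 0.198) sit within binomial sampling
error of the planted 0.3/0.4/0.2; and the species planted on both
continents is called cosmopolitan while the single-lake species is called
endemic.

Each mOTU partition, catalog and abundance matrix has `tidy()` /
`glance()` accessors and an `autoplot()` display (mOTU sizes, likelihood
margins, abundance heatmaps, trait heatmaps).

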