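---
title: "Genome-resolved mOTU analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-resolved mOTU analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motukit)
library(dplyr)
```

motukit chains five stages: a synthetic-community generator, ANI-based
mOTU clustering, incompleteness-aware core/accessory partitioning,
competitive-mapping abundance profiles, and trait/biogeography
classification. This vignette explains the model behind each stage, the
parameters that matter, and the choices made where the design was
genuinely open.

## Why incompleteness is the central nuisance parameter

Draft genomes binned from metagenome assemblies (MAGs) or amplified from
single cells (SAGs) are incomplete: a genome with CheckM-style
completeness 0.8 is expected to be missing ~20% of its genes purely
through assembly and binning loss. Any question of the form "does species
X carry gene Y" must therefore separate *absent from the population* from
*missed in this draft*. Every stage below either conditions on
completeness (the gene classifier), sidesteps it (ANI on whatever sequence
is present), or applies explicit quality tiers (clustering).

## mOTU clustering

**ANI estimation.** Genomes are reduced to their set of canonical k-mers
(k = 21 by default; the lexicographic minimum of each k-mer and its
reverse complement, so strand is irrelevant). For two sets with Jaccard
similarity $J$, the per-base divergence is estimated with the MinHash
transform

$$D = -\frac{1}{k}\,\ln\!\frac{2J}{1+J}, \qquad \mathrm{ANI} = 100\,(1-D),$$

floored at 0 for disjoint sets. At desk scale (genomes of 10 kb – 1 Mb)
the *full* k-mer set is used rather than a fixed-size MinHash sketch —
there is no sampling error to trade away; `sketch_size` enables bottom-s
sketching under a fixed deterministic hash for larger inputs. On
substitution-simulated pairs of 100 kb genomes the estimator is within
±0.5 percentage points of the true identity across 96–99.5% (the
acceptance suite measures ~0.17 worst-case). Externally computed ANI
tables in the common five-column TSV dialect can be imported instead;
directed pairs are symmetrized by their arithmetic mean, a documented
choice since external tools report two directed values and the clustering
needs one.

**Two-tier clustering.** Genomes with completeness ≥ 70% and
contamination ≤ 5% are *seeds*. Seeds are linked when ANI exceeds 95%
("above" is implemented strictly, `>`; the comparison is configurable),
and connected components — including singletons — become mOTUs. The
transitive closure matters: A–B at 97 and B–C at 96 join A and C even at
ANI(A, C) = 93. Genomes at 50–70% completeness are *recruited* into an
mOTU when they exceed the ANI threshold to at least one of its seeds; a
recruit qualifying for several mOTUs goes to the one with the highest
mean ANI over its seed members (missing pairs count 0), ties broken by
mOTU id — the tie rule is ours, chosen for determinism. Everything else is
kept in the catalog as `excluded` with a reason (`low_completeness`,
`high_contamination`, `unrecruited`), never silently dropped. mOTU ids are
assigned by decreasing size, then smallest member id; the representative
is the most complete seed, ties broken by lower contamination then id.

## Core/accessory partitioning

For gene $g$ with observed presence $x_{gi} \in \{0,1\}$ over members
$i = 1..N$ with completeness $c_i$:

* **core model** — the gene is truly in every genome and absences are
  detection failures:
  $\mathrm{LL}_\mathrm{core} = \sum_{i: x=1} \ln c_i + \sum_{i: x=0} \ln(1-c_i)$;
* **accessory model** — the gene segregates like a typical accessory gene:
  $\mathrm{LL}_\mathrm{acc} = \sum_{i: x=1} \ln p_i + \sum_{i: x=0} \ln(1-p_i)$,
  with $p_i$ = (accessory genes observed in genome $i$) / (distinct
  accessory genes in the mOTU).

A gene is core iff $\mathrm{LL}_\mathrm{core} > \mathrm{LL}_\mathrm{acc}$.
Because $p_i$ depends on which genes are accessory, the assignment is
iterated: initialize core as genes at observed frequency ≥ mean($c_i$) —
coupling the starting cut to data quality rather than a fixed 50% — then
recompute $p_i$ and reassign until a fixed point. These Bernoulli-product
forms and the iteration are this package's own reconstruction of the
one-sentence comparison such classifications are usually described by;
equivalence with any external pangenome tool is not claimed.

Numerical choices: probabilities are clamped to $[10^{-3}, 1-10^{-3}]$ so
"100% complete" genomes cannot produce infinite log-likelihoods; an empty
accessory set sets $p_i = 10^{-3}$; if the assignment cycles (possible in
principle for adversarial matrices), the lexicographically smallest
assignment in the cycle is returned with `converged = FALSE`. The
procedure is deterministic and invariant to row/column order (genes and
genomes are sorted internally). Completeness re-estimation
(`reestimate_completeness = TRUE`) replaces $c_i$ after each sweep with
the fraction of current core genes observed in genome $i$; it is off by
default because single-copy-marker completeness estimates are treated as
authoritative inputs. Contamination is *not* modeled in the likelihood —
with the 5% catalog cap its effect is second-order — and this is a known
limitation.

Hand-checkable anchor (N = 10, $c_i = 0.9$, $p_i = 0.3$): a gene present
in 9/10 scores $9\ln 0.9 + \ln 0.1 \approx -3.251$ under the core model
versus $\approx -11.19$ accessory (core wins); present in 1/10 scores
$\approx -20.83$ versus $\approx -4.414$ (accessory wins).

Two limits pin the behavior. With all $c_i \to 1$ the classifier must
equal the presence-in-all indicator — absences can no longer be blamed on
incompleteness — and the tests verify this exactly. And a gene observed in
*zero* members is never classified at all: it is reported `absent`. That
absence standard (a gene must be missing from every MAG and SAG of the
mOTU to be called missing from the population) is what replication across
members buys over single-representative analyses.

## Abundance profiles

Libraries are subsampled without replacement to a fixed size
(default 1,000,000 reads) so samples are comparable; a library below the
target is used whole with a warning. The 100%-identity criterion is
implemented literally: a read counts only if it occurs as an exact
full-length substring of a genome, on either strand — no mismatches, no
clipping. The index is a hashed set of every read-length window of each
genome and its reverse complement; exact-by-construction and fast at desk
scale (an alternative k-mer-seeded design answers the same query and
would only matter for much larger references).

Reads are assigned *competitively*: all catalog genomes are indexed
together. A read matching genomes of one mOTU adds 1 to it; a read
matching $k > 1$ mOTUs adds $1/k$ to each. Equal splitting is our choice —
deterministic and count-conserving where random assignment is not
reproducible and discarding breaks the mass balance; both alternatives are
available (`ambiguous = "discard"/"random"`). The invariant
$\sum_\mathrm{mOTU} \mathrm{abundance} + \mathrm{unmapped} = 1$ holds
exactly, fractional counts included.

Counts are normalized per metagenome, averaged per site with an
*unweighted* mean that includes samples where the mOTU is absent (zeros),
and flagged present at mean abundance ≥ 0.0003 (0.03%). The boundary is
inclusive — stated cutoffs are read as "at and above" — and raising the
cutoff can only reduce presences (tested). Depth-resolved views are just
the unaveraged per-sample matrix joined to depth metadata; no
interpolation.

## Traits and biogeography

Marker hits (pre-reduced 4-column or standard 12-column tabular alignment
format plus query lengths) are filtered at query coverage ≥ 80% and
identity ≥ 50%, except 80% for PsaA-class markers; comparisons are
inclusive, and coverage follows the query-length convention. A marker
absent from every member is `absent`; otherwise its presence profile is
scored by the same likelihood rule as any gene, using the mOTU's fitted
carriage probabilities — so the trait matrix is consistent with the
pangenome partition by construction, not by a separate frequency
heuristic.

Biogeography combines two evidence channels — member-genome origins and
read-mapping occupancy, reported separately — into one location set. The
rule table: **cosmopolitan** = ≥ 2 continents; **endemic** = confined to a
single site *or* a single region; **regional** = otherwise; **unknown** =
no located evidence. The three-level scheme with explicit boundaries
replaces narrative categories ("found in just one lake, in one area, or
just in Scandinavia") for the sake of testability; "endemic to a region"
is deliberately allowed to span several sites of that region. Continents
are metadata, never hardcoded geography. Adding occupancy evidence can
promote (endemic → regional → cosmopolitan) but never demote.

## The synthetic generator: what it emulates and what it does not

Each species is a shared core-gene set plus an accessory pool whose genes
segregate independently at a fixed frequency; genomes are degraded by
Bernoulli gene loss at (1 − completeness) and optional foreign-gene
contamination; sequences diverge from a per-species random ancestor by
independent substitutions at rate $(100 - \mathrm{ANI}_w)/200$ per base,
so a pair of members differs at about $(100-\mathrm{ANI}_w)\%$ of sites;
reads are drawn uniformly from member genomes in proportion to planted
abundances, with the remainder from a background sequence rejection-checked
to share no 31-mers with any genome (so background reads can never map at
100% identity and the unmapped denominator is meaningful).

Defaults chosen once as realistic study conditions: read length 150 bases
(standard short-read length), within-species ANI 98 (inside the >95%
species boundary), accessory carriage frequency 0.3, completeness 0.95
and contamination 0 unless a scenario sets them (real collections span
50–100% completeness with mean near 90; completeness is exposed as a
per-genome vector rather than an assumed distribution precisely because
that distribution is collection-specific). Substitution-only mutations
(no indels) keep exact-match mapping and Hamming-based identity
verifiable; single-end reads suffice because the mapping criterion is
per-read; gene content and sequence are generated independently because
the gene analysis operates on annotation-derived presence tables, not
coordinates. None of read-quality profiles, chimeras, assembly or binning
are simulated — so passing tests demonstrate correctness of the inference
chain under its stated model, not robustness to assembler or binner
artifacts.

All generators are bit-reproducible given a seed; multi-stage simulations
derive per-stage child seeds from the master seed (and the read
background uses its own derived stream so it can never replay the genome
generator's draws).

## Problem sizes and verification

The test suite and `scripts/acceptance.R` run everything at desk scale,
chosen so the full chain exercises in minutes: 5 species × 8 genomes of
100 kb for clustering recovery (adjusted Rand index 1.0 against the
planted partition, with the external ARI implementation as the oracle);
100 kb pairs at 96/98/99.5% identity for estimator calibration (±0.5
points); 20 genomes × 2000 genes for classifier recovery (F1 ≥ 0.95 at
completeness 0.9, exact at 0.999); 100,000-read subsamples for abundance
recovery (within $3\sqrt{a(1-a)/R}$ of a planted 20%, mass balance exact);
and a 5-seed two-continent community for biogeography (exact). Clustering
is additionally cross-checked against an exhaustive union-find on random
instances, and the likelihood classifier against hand-computed values.

## Known limitations

* ANI is k-mer-based; it is calibrated for substitution divergence and
  will read low under heavy indel or rearrangement divergence.
* Contamination enters only through the 5% exclusion threshold, not the
  likelihood.
* The equal-split rule for cross-mOTU ambiguous reads is a modeling
  choice; at 100% identity and >95% inter-mOTU divergence such reads are
  rare (conserved regions), but abundant shared plasmids would be split,
  not resolved.
* The `regional` category is only as meaningful as the caller's region
  labels.
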