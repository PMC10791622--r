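---
title: "Delimiting genomovars and strains from ANI distributions and metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delimiting genomovars and strains from ANI distributions and metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genomovaR)
```

## The problem

Bacterial species harbour enormous internal diversity, and "strain" has no
operational, sequence-based definition that different studies apply
consistently. When many isolates of one species are sequenced, the
distribution of pairwise genome-aggregate average nucleotide identity (ANI)
values is not uniform near its top end: values just below the near-identity
cluster are strongly depleted, leaving a natural discontinuity (a "gap"),
typically somewhere around 99.2–99.8% ANI. That gap suggests two nested,
data-driven intra-species units:

* **genomovar** — all genomes connected at ANI strictly above the lower edge
  of the gap (default threshold 99.5%);
* **strain** — genomes sharing ANI > 99.99% *and* gene content > 99.0%, a
  level chosen to sit above typical sequencing/assembly noise (which
  re-assembly of split read sets places at ~99.99% ANI and ~99% shared
  genome).

Once genomovars are delimited, competitive recruitment of metagenomic reads
against one representative genome per genomovar measures each genomovar's
in-situ abundance, and a leave-genomes-out accumulation curve extrapolated on
a log scale estimates how many genomovars the whole natural population
contains.

`genomovaR` implements this entire chain as composable functions, together
with a synthetic population generator that plants all of the structure the
method is supposed to find, so that every stage can be tested against known
truth without any external data.

## Pipeline overview

| Stage | Functions |
|---|---|
| I/O for FASTA, ANI tables, 12-column hit tables | `read_genomes()`, `read_ani_table()`, `read_hit_table()`, writers |
| Fragment-based ANI | `estimate_ani()`, `ani_all_vs_all()` |
| Gap detection | `ani_bin_stats()`, `expected_uniform_per_bin()`, `depletion_ratio()`, `kde_extrema()`, `bootstrap_gap()` |
| Unit delimitation | `assign_genomovars()`, `assign_strains()`, `pick_representatives()` |
| Orthology and alleles | `build_ogs()`, `core_single_copy_ogs()`, `dereplicate_alleles()`, `allele_catalog()`, `allele_sharing()`, `shared_gene_fraction()` |
| Read recruitment | `best_hits()`, `species_filter()`, `genomovar_assign()`, `recruit_profile()` |
| Richness | `read_cover_matrix()`, `accumulation_curve()`, `fit_extrapolate()` |
| Synthetic truth | `population_spec()`, `generate_population()`, `simulate_reads()`, `replicate_with_noise()`, `truth_*()` oracles |

All numeric thresholds live in `analysis_config()` and default to the values
above (species read filter ≥95% identity and ≥70% read coverage; genomovar
read rule ≥99.3%; KDE bandwidth factor 0.15; 10,000 bootstrap iterations; 100
accumulation permutations; regression window 20–100 genomes; 99% prediction
interval).

## Models and numerical choices

### Fragment-based ANI

`estimate_ani()` chops the query into non-overlapping 1000 bp fragments (per
contig, dropping sub-length tails and fragments over 10% N), seeds each
fragment with exact 15-mers at up to eight offsets, and scores candidate
placements by ungapped comparison. A placement that runs off a subject contig
edge is scored over the overlapping part only (at least one third of the
fragment), so assembly fragmentation costs at most an occasional fragment
instead of every boundary-spanning one. ANI is the mean identity of accepted
fragments (floor 70%); the aligned fraction is the percent of fragments
accepted. Multiple seed offsets matter: at 3% divergence a single 15-mer seed
is clean only ~63% of the time, and losing fragments biases ANI.

Limitations, by construction: extension is ungapped, so the estimator is
exact only for indel-free genomes (the synthetic regime, where it reproduces
the Hamming-identity oracle to numerical precision). For real draft genomes
indels shift coordinates and the supported path is an externally computed ANI
table read with `read_ani_table()`. When two genomes differ in accessory
content, fragments from genes absent in the subject lower the aligned
fraction, and mosaic boundary fragments can carry partial-overlap identities;
this mirrors how fragment-based ANI tools behave on real gene-content
differences.

### Gap detection

Two complementary views are computed. The *binned depletion* view counts ANI
values in half-open 0.1-point bins and contrasts each bin with the
expectation under a uniform spread of the in-range values
(`expected_uniform_per_bin()`; e.g. 578 values over one ANI point give 57.8
per bin). The *density* view evaluates a Gaussian KDE with bandwidth equal to
0.15 × the sample standard deviation (the scalar-bandwidth convention of the
usual scientific-computing KDE) on a 1024-point grid over the data range ±3
bandwidths, and takes strict-neighbour local extrema. The deepest valley
inside the search window (default [99, 100]) is the gap estimate;
`bootstrap_gap()` repeats this over resamples (with replacement, seeded) and
reports the 2.5/50/97.5 percentiles of the valley position.

Numerical caveats worth knowing:

* With a bandwidth of 0.15 × sd the KDE is deliberately under-smoothed, so
  *any* sample with mass inside the window shows shallow sampling wiggles
  that count as strict-neighbour valleys. The "no robust gap" flag (more than
  half of the iterations valley-free) therefore triggers when the
  distribution has no mass in the searched intra-species range — the
  appropriate negative control is a unimodal distribution below the window,
  not a unimodal cluster inside it. The *position spread* of the bootstrap
  valley is the informative quantity when mass is present.
* The search window and the bin convention are parameters; the half-open
  convention means a value exactly at a bin edge belongs to the upper bin.

### Genomovar and strain clustering

The clustering rule the thresholds imply is deliberately made measurable:
`assign_genomovars()` takes single-linkage connected components of the graph
with edges ANI > threshold (strictly greater; the threshold convention is
configurable), *and* computes the complete-linkage partition at the same
height as a diagnostic. On gap-separated data all linkages agree and the
`linkage_sensitive` flag stays FALSE; chains straddling the threshold set the
flag and are listed as straddling pairs (within ±0.1 of the threshold)
instead of being silently resolved. Strains require both ANI > 99.99% and
shared gene content > 99.0% (conjunction), are clustered by single linkage,
and are forced to nest inside genomovars (cross-genomovar strain edges are
dropped with a warning). Gene content preferably comes from the orthology
module (`gene_share_matrix()`); the ANI table's aligned fraction is the
documented fallback and the source used is recorded in the output. Mobile
element differences are deliberately *not* used to override the ANI rule.
Representatives are ANI medoids (maximum summed ANI to co-members), ties
broken lexicographically.

### Orthology and alleles

Orthologous groups are connected components of the reciprocal-best-hit graph
between genomes (90% identity, 90% query coverage; score = identity ×
alignment length), plus within-genome near-duplicate edges so that recent
paralogs land in the component and mark it non-single-copy. A plain
components rule replaces the MCL clustering used by some pipelines: it is
deterministic, dependency-free, and identical on single-copy, gap-separated
data. Core single-copy OGs are those with exactly one member in every
genome. Alleles of a core gene are dereplicated greedily in lexicographic
gene-id order at a ≥99.8% global-identity floor; for equal-length sequences
the identity is the exact Hamming value, otherwise a global alignment scored
over the mean length (end gaps count against identity). Greedy clustering is
order-dependent only when identities fall inside a narrow band around the
floor; away from that band it provably matches single-linkage, which is the
oracle the tests compare against.

### Competitive recruitment

Per read, only the best hit by bit score counts; exact bit-score ties across
genomes are discarded (conserved regions otherwise double-count). The species
read set requires ≥95% identity and ≥70% read coverage. Genomovar-level
assignment is exclusive: a read counts for a genomovar only when it matches
that genomovar's representative at ≥99.3% and every other representative
below 99.3% — with 150 bp reads this tolerates exactly one mismatch
(149/150 = 99.33%). The coverage rule is applied at this step too
(conservative; configurable). Abundances are normalised by representative
genome length and total metagenome reads; the per-genomovar population
fraction uses length-corrected counts. The accounting is exact by
construction: species reads = counted + tie-discarded + sub-threshold +
ambiguous, asserted on every profile.

An intrinsic limit of the 99.3% rule, visible in the synthetic world and
inherent to short reads: reads from regions shared at ≤1 mismatch with a
*sister* genomovar's representative become ambiguous or tied, and with a
per-base error rate of 0.001 the chance a read survives with at most one
error is P(Bin(150, 0.001) ≤ 1) = 0.98988 — fractionally below 99%. Reads
carrying two errors that both convert diagnostic sites can even be assigned
to a close sister genomovar at ≥99.3% identity; this is rare (order 1 in
10^5) but nonzero, and it is a property of the method, not of the
implementation.

### Richness extrapolation

For the accumulation analysis every qualifying match is preserved (not
best-only): a read is covered when at least one included representative
matches it at ≥99.3%. Representatives are added in 100 random orders; after k
genomes the curve records the fraction of species reads covered. The
regression fits log10(k) on the per-step *mean* fraction within the 20–100
genome window by ordinary least squares and extrapolates to full coverage
(f = 1): N̂ = 10^(a + b). Fitting the mean curve rather than the pooled
permutation cloud avoids shrinking the prediction interval by
pseudo-replication (each permutation reuses the same reads); the pooled mode
remains available as a flag for sensitivity analysis. The prediction interval
at f = 1 uses the standard t-based formula with n − 2 degrees of freedom on
the log scale and is back-transformed; logarithm base does not affect the
back-transformed estimate. A non-positive slope flags the extrapolation
invalid rather than producing a nonsense estimate. The species-read
denominator is the count of reads matching *any* reference at ≥95%.

## The synthetic world

`generate_population()` emulates the observed structure of a natural
intra-species population:

* **Planted ANI bands.** Divergence intervals are *pairwise* targets; branch
  mutation rates are drawn from half the interval, since two lineages split
  from a common ancestor add up. Defaults: between-genomovar pairwise
  divergence 0.008–0.03 (ANI ≈ 97.0–99.2), within-genomovar 0.001–0.002
  (ANI 99.8–99.9), within-strain 4 × 10⁻⁵ (ANI ≈ 99.996). The forbidden band
  (99.2, 99.8) is free of genome pairs by construction and asserted at
  generation time. The within-genomovar lower bound is kept strictly positive
  so that distinct strains remain distinguishable at the 99.99% threshold —
  with a bound of zero two strains could coincide and no method could
  recover the planted strain partition.
* **Founder phylogeny with sister pairs.** A pure star phylogeny almost never
  produces genome pairs near the upper edge of the between-genomovar range,
  which real populations do show; a fifth of the genomovars therefore come as
  low-abundance sister pairs whose pairwise ANI approaches the gap edge
  (~99.0–99.2), with the rest spread star-like across the full range. This
  makes the empirical gap match the planted band and reproduces the
  real-world difficulty that sister genomovars share many 150 bp windows.
* **Gene architecture.** 40 core genes of 900 bp plus 2 fully conserved
  (rRNA-like, zero-divergence) genes and ~12 kb of intergenic backbone make
  up the 50 kb universal genome; a 20-family accessory pool is carried per
  genomovar with loss probability 0.3. Strain- and isolate-level mutations
  are confined to the backbone, so members of one genomovar share 100% of
  core-gene alleles (matching the observed within-genomovar allele
  cohesion) and the planted allele count per core gene is exactly the number
  of distinct founder alleles. The conserved genes generate genuine
  recruitment ties and saturated allele sharing between genomovars, the
  "noise" real rRNA operons cause. (The backbone must be large enough to
  absorb the within-genomovar divergence; `population_spec()` enforces
  this.)
* **No indels anywhere.** This is the key simplification: homologous
  coordinates are shared population-wide, so the identity of any read or
  fragment to any genome is exactly computable without alignment, and every
  oracle (`truth_ani_table()`, `truth_gene_share()`,
  `truth_allele_counts()`, the per-read hit table) is cheap and exact.
* **Reads.** `simulate_reads()` draws read sources from a geometric (default
  ratio 0.8) or lognormal rank-abundance distribution (the long-tailed "rare
  biosphere" shape), plants independent per-base substitution errors
  (default 0.001), and emits the exact competitive hit table, with bit scores
  2·matches − 3·mismatches so that identical windows produce genuine ties. A
  read is marked *genomovar-unique* in the truth manifest when its error-free
  window is identical to its own genomovar's representative and ≥2 mismatches
  from every other representative.

What a green test on this world does **not** establish: behaviour on real
draft assemblies (indels, rearrangements, contamination, chimeric contigs),
agreement with any particular external ANI or search tool, robustness to
quality-dependent or indel sequencing errors, or recombination/gene-flow
dynamics — none of which are modelled.

### Calibration of the richness test world

The planted-richness recovery suite uses 200 genomovars with 120 sampled in
proportion to abundance (emulating cultivation) at reduced scale (20 kb
genomes, 10⁴ reads). The geometric ratio was calibrated once for
log-linearity of the accumulation curve in the 20–100 window, as the
procedure assumes: the Pearson correlation was flat (≈0.984) across ratios
0.95–0.98, so the plateau midpoint 0.96 was fixed and not revisited. Residual
curvature comes from cross-mapping — reads of unsampled genomovars partially
covered by close relatives — which is equally present in real competitive
recruitment.

## Known limitations

* The fragment ANI estimator is a validation tool for the synthetic regime,
  not a replacement for established ANI software on real genomes.
* Published isolate-collection analyses sometimes carry one-off bookkeeping
  quirks — a pairwise-comparison count of 9,454 where 138 genomes give
  138·137/2 = 9,453, or a core-gene tally quoted as 793 in one place and 797
  in another. `genomovaR` always reports n(n−1)/2 unordered pairs and its own
  computed counts, and makes no attempt to reproduce such figures.
* The 99.3% read rule's recovery ceiling (98.99% under a 0.001 error rate,
  see above) means per-genomovar read counts are slight undercounts; the
  abundance normalisation does not correct for this.
* `bootstrap_gap()`'s flag semantics depend on the search window (see gap
  section); users should inspect the bootstrap position spread, and the
  per-iteration extrema are retained for that purpose.

## A minimal run

```{r example, eval = FALSE}
spec <- population_spec(rng_seed = 1)
pop <- generate_population(spec)
tab <- truth_ani_table(pop)

gap <- bootstrap_gap(tab$ani, analysis_config(), iterations = 200, seed = 2)
asn <- assign_genomovars(tab)
reps <- pick_representatives(asn, tab)

sim <- simulate_reads(pop, n_reads = 20000, targets = unname(reps),
                      emit_reads = FALSE, seed = 3)
prof <- recruit_profile(sim$hits, reps,
                        genome_lengths(as_genome_set(pop, unname(reps))),
                        total_reads = 40000)
prof
```

The same chain, extended with the orthology and richness stages, is what
`scripts/acceptance.R` runs end-to-end.
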