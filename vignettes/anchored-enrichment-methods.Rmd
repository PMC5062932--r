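---
title: "Methods: anchored-enrichment probe design and post-capture processing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anchored-enrichment probe design and post-capture processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`anchorforge` implements the two computational halves of an anchored hybrid
enrichment (AHE) workflow for phylogenomics in non-model clades:

1. **Design**: from ortholog alignments plus reference genomes, select
   conserved target regions, avoid exon boundaries and high-copy repeats,
   and tile 120-bp capture probes into a fixed-capacity kit.
2. **Processing**: from assembled per-sample consensus sequences, recover
   single-copy ortholog sets, trim alignments, and build a partitioned
   supermatrix with informativeness statistics.

A seeded clade simulator provides ground truth (gene structure, planted
repeats, planted duplications) for every stage, so the whole toolkit can be
validated end to end without external data.

# The design pipeline (`run_design`)

## Candidate loci

An input alignment is a candidate anchor locus when it has **at least 6
taxa** and contains at least one 120-bp sliding window whose **mean pairwise
identity is strictly above 50 %**. Identity for a pair of rows is computed
over *comparable* columns only (both rows non-gap, non-N); the window score
averages over all row pairs. A window with no comparable pair contributes
nothing. `window_identity()` exposes the statistic; the sweep is
incremental (cumulative sums over per-pair match/comparable indicators), so
a full scan is linear in alignment length per pair.

*Open choice*: "pairwise sequence identity of a window" could be read as the
minimum over pairs or the mean. We use the **mean**, which matches the
notion of a conserved anchor core shared across the clade and is robust to
one divergent row; the minimum reading would let a single rogue sequence
veto a locus that is otherwise an excellent anchor.

## Exon-boundary mapping

Probes that span splice junctions fail at capture, so targets must be
boundary-free. Two independent mappers are provided:

* `map_exons_by_kmer()` — exact **40-mer** chaining of a transcript against
  its genome. Matching 40-mer offsets are grouped into maximal colinear
  diagonal blocks, chained by dynamic programming maximizing transcript
  coverage (allowing up to `min(k-1, 5)` bases of transcript overlap between
  blocks, since a chance 1-base junction match can extend a block past the
  true junction). A boundary is called where consecutive chained blocks are
  adjacent in the transcript but separated in the genome (positive intron
  length). Both genome strands are tried; the better-covering strand wins.
  Seed k-mers occurring at more than `max_hits = 64` genome positions —
  seeds falling inside high-copy repeats — carry no placement information
  and are skipped, the standard repetitive-seed treatment in
  seed-and-chain mappers; without it a repeat-spanning transcript can seed
  one diagonal per repeat copy and stall the chaining step.
* `map_exons_by_reads()` — for taxa with raw reads but no genome: reads are
  placed on the transcript (seed-and-extend, both orientations) and a
  boundary is called at positions where **≥ 5** reads show a discordant
  pattern: well-matched on one side of the position, **> 20 %** mismatches
  within a **30-bp** flank on the other. Adjacent candidate positions are
  merged to the point of maximal contrast.

Numerical caveat recorded as a limitation: when the first intron base
happens to equal the first base of the next exon (or symmetrically at the
intron's 3' end), the junction position is genuinely unidentifiable from
sequence alone and the k-mer mapper may report it shifted by the length of
that coincidental run. This is a property of the data, not the algorithm;
the simulator's constructed-gene fixtures avoid it so exactness can be
asserted, while evolved-sequence tests assert recovery within the
ambiguity.

## Targets

Within each candidate locus, `select_preliminary_targets()` cuts at every
boundary, drops columns outside maximal gap-free runs, and keeps regions of
**≥ 150** alignment columns. Rows that are entirely gap/N are removed
first. Each retained region records its mean pairwise identity.

## Homolog scan and representation filter

When transcriptome assemblies are available, each target is searched
against them by best local alignment (`Biostrings::pairwiseAlignment`,
local mode, match +1 / mismatch −1, gap open 5 / extend 2, both strands).
A hit is kept only when its match fraction is **at least 55 %** (a best hit
at 0.549… is rejected). Assembled locus sets then pass a representation
filter: all required anchor taxa present, and **no more than 2** rows
shorter than **80 %** of the longest anchor row.

Multiple-alignment of scanned hits is delegated to an external aligner;
the package records the exact command (`mafft --genafpair --maxiterate
1000`) in the run manifest rather than shelling out, because simulated
sequences are generated without indels and stack directly. On real data the
recorded command is the contract to execute between `assemble_locus_set()`
and the downstream steps.

## Repeat masking

`build_kmer_db()` enumerates every **15-mer** of every target alignment row
together with **all 45 Hamming-distance-1 neighbours**, keyed to the
alignment column of the k-mer start. `tally_genome()` counts occurrences of
those k-mers in each genome on **both strands** (exact dictionary counts via
a `data.table` join — no heuristics). Any column whose tally in *any*
genome is **strictly above 100,000** is masked in all rows
(`mask_high_copy()`). Masked columns are treated as N for tiling and
output.

*Open choice*: the tally-to-column attribution masks the k-mer's start
column. Since high-copy elements (microsatellites, mobile elements) occupy
runs of columns far longer than k, per-start-column masking blankets the
repeat while leaving flanking unique sequence available for probes.

## Tiling and kit capacity

`tile_probes()` places **120-bp** probes at **4.0× tiling density**
(spacing `round(120/4) = 30` bases), with a final probe shifted flush to
the region end; any probe overlapping a masked column is discarded;
regions under 120 bp yield none. After exact-sequence deduplication
(`dedupe_probes()`), `replicate_to_capacity()` fills the kit to exactly
**57,700** probes by cyclic +1 replication ordered shortest-locus-first, so
short loci — which contribute the fewest distinct probes and are most at
risk of capture failure — receive extra copies first. A distinct-probe set
larger than the capacity is an error, not a silent truncation.

# The processing pipeline (`run_process`)

## Read support and ortholog clustering

Consensus sequences assembled from **fewer than 35 reads** are removed
(`filter_consensus()`; a record with unknown support is an error naming the
offending id). Each sequence is then reduced to a **20-mer profile**: the
union of all contiguous 20-mers and all every-third-position 20-mers
(span 58), ambiguity-free only. Pairwise distance is Jaccard on these
sets: `1 − |A∩B| / |A∪B|`.

Clustering is agglomerative average linkage with a **hard species
constraint**: two clusters may merge only when their species sets are
disjoint, so no cluster ever contains two sequences from one species —
paralogs are forced apart by construction. Merging is deterministic:
minimal average distance, ties broken lexicographically on the sorted pair
of smallest member ids. Clusters retaining **at least 75 %** of the species
in the study are kept (`filter_clusters()`; exactly 75 % is kept).

*Open choice*: Jaccard over the union (rather than over the smaller set)
is used because it penalizes length mismatch between fragments, which is
the desired behaviour when fragmentary paralogs shadow full-length
orthologs.

## Trimming

`trim_alignment()` composes three column rules, in order:

1. `good_sites()` — a column is *good* when the modal base (gaps and N
   excluded) accounts for **strictly more than 70 %** of its non-missing
   cells, with at least 2 bases present.
2. `mask_low_quality()` — every **20-column** window containing **fewer
   than 10** good columns is masked across the whole alignment (windows
   slide by 1; masked cells become N on output).
3. `drop_sparse_columns()` — columns with **fewer than 10 unmasked,
   non-gap bases** are deleted outright. Note this is an absolute count:
   alignments with fewer than 10 rows cannot survive it, which matches the
   intended scale of clade-wide studies (tens of taxa).

The composition is idempotent: trimming a trimmed alignment is a no-op.

## Supermatrix and statistics

`concatenate()` lays kept loci side by side over the union of taxa, filling
absent taxa with `?` and masked cells with `N`, and emits a 1-based
inclusive partition table. Outputs are relaxed PHYLIP plus a
`DNA, locus = start-end` partition file. Statistics: counts of variable
and parsimony-informative sites (informative = ≥ 2 states each carried by
≥ 2 sequences, missing symbols excluded), percent missingness,
per-locus informativeness, a PIC-by-offset profile around each locus's
anchor centre, and an OLS regression of informative-site count on locus
length (slope, intercept, adjusted R², slope p-value; < 3 loci or
zero length variance are errors).

Run manifests record downstream tree-inference contracts (RAxML GTRGAMMA
with 1000 random addition sequences and 1000 bootstrap replicates; ASTRAL
over per-locus trees) without executing them.

# The simulator (`simulate_clade`)

`sim_spec()` fixes every stochastic element from one integer seed; named
substreams (`derive_seed(seed, "stream")`) keep stages independently
reproducible. A birth–death tree (`ape::rphylo`) is rescaled to
`tree_height`; each locus gets 1–3 exons (150–400 bp) separated by introns
(80–300 bp). Substitution is exact Jukes–Cantor applied per branch
(`p = 3/4 (1 − e^{−4t/3})`), which composes correctly along paths.
Rate structure:

* introns evolve at **3×** the exon rate;
* a **160-bp anchor span** centred on the spliced transcript evolves at
  **0.25×** — the conserved core that makes a locus an anchor in the first
  place. Without this heterogeneity a deep clade has no conserved windows
  and the design funnel is empty by construction, which would make the
  simulator a poor emulation of anchor loci.

Planted structure: a microsatellite (default `CAG` × 150,000 copies —
deliberately above the 100,000-count masking threshold, since a "high-copy
element" is by definition one the mask must catch) embedded in a target
exon and appended to the genome; gene duplications cloned at the MRCA of
named taxa with extra inter-copy divergence (default calibration: planted
copies ~15 % apart while within-copy divergence stays below ~3 % on
shallow trees), so ortholog clustering has a known answer. Reads are
error-prone uniform fragments; consensus sets draw negative-binomial read
support so the 35-read filter has something to act on.

**What the simulator does not model**: indels (alignments stack), selection
or rate variation beyond the intron/anchor profile, coalescent gene-tree
discordance, GC bias, sequencing-adapter artefacts, and assembly chimerism.
These are deliberately out of scope: the simulator exists to give every
algorithm a checkable truth, not to be a realistic genome generator.

# Conventions and numerics

* Internal coordinates are **0-based half-open**; everything on disk
  (partition tables, mask reports, boundary tables) is 1-based inclusive.
* Every threshold's strictness is as printed above and is pinned by a
  dedicated boundary test (e.g. a 100,000 tally does not mask, 100,001
  does; 34 reads are dropped, 35 kept).
* All randomness flows from a single user seed through `derive_seed()`
  (31-bit multiplicative mixing), so derived seeds are valid everywhere R
  accepts a seed, and identical configurations reproduce byte-identical
  output files (asserted via md5 in the test suite).
* Problem sizes in examples and tests (tens of species, tens of loci,
  kb-scale genomes) are the package's own desk-scale choices so that the
  full pipeline runs in seconds; all thresholds are nevertheless the
  full-scale defaults, and capacity replication is exercised at the real
  57,700-probe kit size.

# Worked example

```{r example}
library(anchorforge)

spec <- sim_spec(seed = 1, n_species = 12, n_loci = 30)
sim  <- simulate_clade(spec)

# design: ortholog alignments from the clade's transcripts + genomes
loci <- lapply(split(sim$truth$exon_boundaries,
                     sim$truth$exon_boundaries$locus), function(rows) {
  rows <- rows[rows$copy == 1, ]
  seqs <- vapply(seq_len(nrow(rows)), function(i) {
    tr <- sim$transcriptomes[[rows$species[i]]]
    tr$sequence[tr$id == rows$transcript_id[i]]
  }, character(1))
  aligned_locus(sprintf("L%03d", rows$locus[1]),
                setNames(seqs, rows$transcript_id), taxa = rows$species)
})
design <- run_design(loci, pipeline_config(), genomes = sim$genomes)
design$funnel

# processing: consensus sequences back to a supermatrix
cs <- simulate_consensus_set(sim)
recs <- cs$records
recs$locus <- cs$truth$locus[match(recs$id, cs$truth$id)]
proc <- run_process(recs, pipeline_config())
proc$stats
proc$regression
```
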