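---
title: "Curating exon-capture markers and refining baits with gcapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating exon-capture markers and refining baits with gcapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcapr)
```

## The problem

Exon capture (target enrichment) subsamples a genome by hybridizing
synthetic 120-nt baits to a sheared DNA library and sequencing what sticks.
For phylogenomics across a group as old and diverse as the ray-finned
fishes, the raw output of a capture experiment needs substantial curation
before the markers are trustworthy and the bait set is economical:

1. **Target identification.** Assembled contigs must be matched back to
   the bait loci. Because baits and targets can be quite divergent across
   families, matching is done in protein space: each contig is translated
   in all six reading frames and aligned locally to the bait's amino-acid
   sequence. The bait-covered part of the best alignment is the exon; the
   overhang on either side is flanking sequence, captured by hitchhiking.
2. **Paralog screening.** A captured sequence whose best genomic hit lies
   outside the locus's annotated target region is likely a paralog;
   keeping it would distort the phylogeny, so it is excluded.
3. **Marker selection.** Results from multiple capture projects are merged
   into a loci × taxa matrix; taxa with too few captured loci are dropped
   (strictly more than 3,000 to keep, at the scale the pipeline is built
   for), and only *phylogenetically decisive* loci are retained — loci
   sampled in every clade group whose relationships the analysis
   addresses.
4. **A posteriori bait refinement.** Pilot read-depth data expose
   low-complexity regions that escaped a priori repeat masking and soak up
   reads at 100× and more above their surroundings. These regions are
   soft-masked, loci left with fewer than 120 unmasked nt are discarded,
   longer loci are split, and baits are re-tiled over the clean segments.
5. **Quality statistics.** Marker length, GC, pairwise p-distance,
   parsimony consistency and retention indices, the RC50 coverage-evenness
   statistic, and flank-vs-coding variability quantify what the curated
   set is good for.

`gcapr` implements each of these steps as composable R functions, plus a
seeded synthetic-data generator so the entire pipeline can be exercised
and tested without any external data.

## Translated local alignment

`smith_waterman_protein()` computes the optimal local alignment under an
affine gap model (Gotoh's three-state recursion, implemented in C++). A
gap of length $L$ costs `gap_open + gap_extend * L`, the BLAST convention.
Defaults are BLOSUM62 with open 11 / extend 1 — the de facto standard for
protein local alignment; no claim is made that any particular published
pipeline used exactly these values, and all three are arguments.

Stop codons in contig translations are rewritten to the `X` wildcard
rather than truncating the frame: an assembly chimera or UTR overhang
should not erase an otherwise solid exon match, and `X` scores neutrally
enough that stops neither anchor nor destroy an alignment. A consequence
is that frameshifted contigs match only up to their best single frame.

`call_target()` scores every contig × frame combination and keeps the best
(`min_score` default 40 matrix units — roughly a dozen conserved residues
— below which a locus is called absent). Ties across contigs are broken
deterministically: longer contig first, then smaller contig id, with a
warning. The exon span is the nucleotide back-projection of the
bait-covered aligned region; partial codons at the alignment ends are
kept, because bait coverage rather than codon structure defines the exon
boundary. Minus-frame hits are reported on the re-oriented (forward)
strand, so downstream consumers never see reverse-complemented exons.

```{r}
bait <- "MSKGEELFTGVVPILVELDGDVNGHKFSVSG"
contig <- paste0("ACGTACGTAC",
                 "ATGAGCAAGGGCGAGGAGCTGTTCACCGGGGTGGTGCCCATCCTGGTCGAGCTGGACGGC",
                 "GACGTAAACGGCCACAAGTTCAGCGTGTCCGGC", "TTGACCCTGA")
call_target("demo_locus", bait, c(contig1 = contig))
```

## Paralog screening

`screen_paralogs()` reduces each query to its best hit (maximal bitscore;
ties by lower e-value, longer alignment, then subject id) and asks whether
the strand-normalized hit interval overlaps the locus's annotated target
region on the same chromosome by at least `min_overlap_bp` (default 1 bp:
any overlap counts as "in the target region"). Hit strand is ignored for
the overlap test. Queries with no hits at all are *retained* by default
with a `no_hit` verdict — absence of evidence is not evidence of paralogy
— but `drop_no_hit = TRUE` excludes them for stricter workflows.

## Merging, taxon filtering, decisiveness

`merge_projects()` resolves duplicate locus/taxon cells in favour of the
longer sequence (projects re-assemble the same individuals with different
success); an exact-length conflict keeps the earlier project and warns.
`filter_taxa()` applies a strictly-greater-than cutoff: a taxon with
exactly the threshold count is dropped, matching "more than N captured"
semantics. `decisive_loci()` operationalizes phylogenetic decisiveness as
*all required clade groups represented*, with `min_taxa_per_group`
defaulting to 1 — one representative suffices to place a group, and
requiring more would discard data without a principled gain. Formal
decisiveness over all possible trees is out of scope; the all-groups
criterion is the operational form used in capture studies of this design,
with the eight major actinopterygian clades (`default_groups()`) as the
default group set.

## Read-depth anomalies and bait re-tiling

`detect_anomalies()` flags a position when its depth is at least
`ratio` (default 100, inclusive for determinism) times the local
background. Two choices deserve comment, since "adjacent regions" admits
several readings:

* The background is the **minimum of the two per-side medians** over
  flanking windows of `flank_window` (default 100) positions. A plateau
  must stand 100-fold above its quieter neighbourhood; using a combined
  two-sided median would let a wide plateau inflate its own background
  and escape detection entirely.
* Flagged positions are excluded from background windows and flagging
  iterates to a fixed point, growing inward from plateau edges. This
  makes detection correct even for plateaus wider than the window, and
  the growth is monotone, so the iteration terminates.

The background is floored at 1, so a zero-coverage neighbourhood cannot
produce division-by-zero, at the cost of strict scale-invariance only
holding when backgrounds are at least 1 — the realistic regime.

`mask_and_segment()` lowercases anomalous spans (soft-masking, so nothing
is deleted) and keeps the maximal unmasked runs of at least 120 nt (one
bait length); loci with no such run are discarded. `tile_baits()` lays
120-nt baits every 60 nt (2× tiling: interior positions are covered
exactly twice), right-aligning the final bait when the segment length is
not a multiple of the step — which can locally raise coverage to 3× near
the segment end, the price of never leaving segment ends under-tiled. A
legacy mode serves whole loci of 100–119 nt with a single bait padded at
the 3′ end with `T`s: thymine forms two hydrogen bonds rather than three,
so T-padding adds the least spurious hybridization energy. Multi-sample
depth profiles are combined position-wise with `combine_depths()`; the
default `max` masks a region anomalous in *any* sample.

## RC50 and coverage evenness

Per-locus coverage is total mapped read bases divided by locus length.
With loci sorted by coverage in descending order, `rc50()` is the
smallest number of top loci whose cumulative mapped data reaches half the
total. A perfectly even experiment gives ⌈n/2⌉; runaway repeat-driven
loci drag it toward 1, so a higher RC50 means more even capture.
Accumulation is in mapped bases by default (consistent with the coverage
definition); `unit = "reads"` accumulates read counts instead, since
either accounting is defensible.

## Parsimony CI and RI

For each alignment column, `ci_ri()` computes the observed Fitch length
$S_i$ (bitmask implementation of the small-parsimony pass; the count is
invariant to rooting, and multifurcations are resolved arbitrarily before
the pass, which does not change the count), the minimum conceivable steps
$M_i$ (distinct observed states − 1), and the maximum $G_i$ (non-missing
taxa − the count of the commonest state). Then

$$\mathrm{CI} = \frac{\sum M_i}{\sum S_i}, \qquad
  \mathrm{RI} = \frac{\sum G_i - \sum S_i}{\sum G_i - \sum M_i}.$$

Gaps, `N` and `?` are treated as missing: the leaf receives the full
state set and can never force a step. All sites are included by default
(the classic default); `informative_only = TRUE` restricts the sums to
parsimony-informative sites. An alignment invariant on the tree has
undefined CI and errors rather than returning a sentinel; RI is `NA` when
$\sum G = \sum M$.

## Flanks, consensus, one best SNP

`filter_flanks()` assigns one primary status per flank, tested in order:
ungapped length `< 20` nt → `too_short`; an aligned gap run longer than
`max_gap_run` (default 30) → `long_indel`; p-distance to the per-locus
majority consensus above `max_pdist` (default 0.6) → `unalignable`. The
20-nt floor is the established cutoff for this filter; the other two
defaults are conservative choices, exposed as arguments because no single
value suits all divergence scales.

`majority_consensus()` takes the most frequent called base per column,
writes IUPAC ambiguity codes on ties, omits columns where gaps hold a
strict majority, and writes `N` where nothing is called.
`select_best_snp()` drops indels and multi-allelic records and keeps one
SNP per locus — the highest QUAL, ties broken by lower missingness then
position. QUAL is a standard proxy for call confidence; "best" has no
sharper published definition for this step. One SNP per locus keeps the
genotype matrix approximately free of within-locus linkage, which is what
a PCA of population structure assumes.

SNP densities (`snp_density()`) count segregating columns (≥ 2 distinct
called bases) over surveyed columns (≥ 2 called bases), scaled to per-kb.
The surveyed denominator approximates the reference length actually
screened, so the statistic is comparable between coding and flank
partitions of very different missingness.

## The synthetic-data generator

`sim_config()` fixes the study conditions; the generators derive
everything from its seed, so a fixed seed gives byte-identical output.
Defaults describe a realistic small capture study: exon lengths uniform
on 100–600 nt in whole codons (coding markers in this class average a few
hundred nt), flanks normal around 800 ± 200 nt per side (flank length
tracks the ~250–800 bp shearing size of capture libraries), per-site
substitution rates 0.035 for coding and 0.050 for flanks (flanks are
less constrained by purifying selection), 10% missingness, and
read-depth plateaus of 50 bp at 200× background in a tenth of loci.

Features deliberately *not* modelled: indels (alignments are generated
gap-free, so flank-filter gap rules are tested on constructed fixtures
instead), rate heterogeneity across sites, sequencing error, assembly
chimerism, and base-composition bias. Tests passing on these fixtures
therefore demonstrate algorithmic correctness — spans recovered, sets
selected, plateaus masked — not robustness to every artefact of real
capture data.

One generator choice matters for truth-table bookkeeping: `protect_ends`
(default 1) shields that many codons at each exon end from mutation. A
mutated terminal residue with a negative substitution score would make
the *optimal* local alignment legitimately shorter than the planted exon,
so without a protected margin the planted span is not a well-defined
truth. Locus-level recovery does not depend on this; only exact span
comparisons do. For parsimony fixtures, `evolve_jc()` runs Jukes–Cantor
evolution along a user tree — the simplest model that generates known
homoplasy structure.

## Problem sizes and numerical choices

The test-suite and the acceptance script run everything at desk scale,
chosen so the full pipeline is exercised in minutes on one core: capture
studies of 12–60 loci × 8–16 taxa, depth profiles of a few hundred
positions, 100-replicate rate-recovery experiments, and exhaustive
parsimony checks over all 4⁴ and 4⁶ site patterns on 4- and 6-taxon
trees. Headline numbers from genome-scale studies (thousands of markers
from dozens of samples) are not reproducible at this scale and are not
claimed; what is verified is that every rule — thresholds, tie-breaks,
boundary conditions — behaves exactly as specified, against brute-force
oracles wherever one exists.

Tie-breaks are deterministic throughout (documented per function), all
threshold comparisons are inclusive (`>=`) unless the rule is stated as
strictly-greater (the taxon filter), and degenerate inputs (empty
alignments, all-zero coverage, invariant alignments) raise errors rather
than returning sentinels.

## Limitations

* Paralog screening by best-hit location cannot detect paralogy when the
  duplicate outscores the true copy *inside* the target region, nor
  resolve the lineage-specific losses that follow ancient whole-genome
  duplication; tree-based filtering is a complementary, out-of-scope
  approach.
* The anomaly detector assumes depth profiles long enough to contain
  genuine background; a locus that is wall-to-wall repeat shows no
  quieter neighbourhood and escapes masking.
* CI/RI are computed on the given tree; they measure homoplasy, not tree
  correctness.
* `read_depth_table()` consumes samtools-depth-style TSV only; BAM
  processing belongs upstream.
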