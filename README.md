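# gcapr — gene capture marker refinement

`gcapr` curates single-copy exon markers from target-enrichment (gene
capture) experiments and refines hybridization bait design *a posteriori*
from pilot sequencing data. It is aimed at phylogenomic studies — its
defaults describe capture panels for ray-finned fishes — but every step is
generic over loci, taxa and clade groupings.

The pipeline it implements:

- **Target identification** — translate assembled contigs in all six
  frames, align them to each bait protein with an affine-gap
  Smith–Waterman (Gotoh) aligner (BLOSUM62, open 11 / extend 1, gap of
  length *L* costs 11 + *L*), and split the best match into the exon (the
  bait-covered region, back-projected to nucleotides) and its flanks.
- **Paralog screening** — a query whose best genomic hit does not overlap
  its annotated target region is flagged as a putative paralog and
  excluded.
- **Marker selection** — merge capture projects into a loci × taxa
  matrix, keep taxa with strictly more than a cutoff of captured loci
  (default 3,000), and keep only *phylogenetically decisive* loci: those
  sampled in every required clade group.
- **Bait refinement** — detect read-depth plateaus ≥ 100× their local
  background (minimum of the two flanking-window medians, iterated so
  wide plateaus cannot hide themselves), soft-mask them in lowercase,
  discard loci left with < 120 unmasked nt, and re-tile 120-nt baits at
  2× (60-nt step), right-aligning the final bait and T-padding whole
  short loci at the 3′ end.
- **Quality statistics** — per-locus length, GC, pairwise p-distance,
  Fitch-parsimony consistency (CI = ΣM/ΣS) and retention
  (RI = (ΣG−ΣS)/(ΣG−ΣM)) indices on a reference tree, and the RC50
  evenness statistic: with loci sorted by read coverage descending, the
  number of top loci that consume half of all mapped data.
- **Flank variability and SNP export** — flank filtering (< 20 nt, long
  indels, unalignable), majority-rule consensus references, per-kb SNP
  densities for coding vs flank partitions, and one-best-SNP-per-locus
  genotype matrices from VCF.
- **Synthetic data** — seeded generators for every input above (contigs,
  depth tables, hit/annotation tables, alignments), so the whole pipeline
  runs and is tested without external data.

## Worked example

```r
library(gcapr)

# a bait protein and a contig carrying its coding sequence + flanks
bait <- "MSKGEELFTGVVPILVELDGDVNGHKFSVSG"
contig <- paste0("ACGTACGTAC",
  "ATGAGCAAGGGCGAGGAGCTGTTCACCGGGGTGGTGCCCATCCTGGTCGAGCTGGACGGC",
  "GACGTAAACGGCCACAAGTTCAGCGTGTCCGGC", "TTGACCCTGA")
call_target("demo_locus", bait, c(contig1 = contig))
#> Target call demo_locus: contig contig1, frame 2, score 152
#>   exon [10,103) with flanks 10/10 nt
```

The call reports the winning contig and reading frame, the alignment
score in BLOSUM62 units, the exon span on the (re-oriented) contig in
0-based half-open coordinates, and the flank lengths.

```r
# refinement: a 50-bp plateau at 200x background is masked and re-tiled
d <- rep(10L, 500); d[201:250] <- 2000L
detect_anomalies(d)
#>      start end
#> [1,]   200 250

tab <- coverage_table(paste0("L", 1:4), rep(100, 4), c(80, 10, 5, 5))
rc50(tab)
#> [1] 1
```

RC50 = 1 here because the top locus alone consumes 80 of 100 mapped
bases — a maximally uneven capture; a perfectly even four-locus table
would give 2.

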