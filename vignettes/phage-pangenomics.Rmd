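---
title: "Delineating phage taxa from genomes: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating phage taxa from genomes: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagepan)
```

# The problem

Genome-based phage taxonomy assigns isolates to species and genera from two
complementary signals: *nucleotide-level intergenomic similarity* (the
VIRIDIC statistic used by the ICTV community, with ~95% as the customary
species line and ~70% for genera) and *gene-content similarity* (shared
protein clusters, summarized per pair as Jaccard percentages and per group
as core/accessory/signature gene counts). `phagepan` implements both
signals, plus a core-genome phylogeny with congruence testing, as one
deterministic pipeline over plain FASTA/GenBank inputs, and ships a
synthetic community generator so that every stage can be exercised and
validated without downloading anything.

The motivating use case is a community of ~45 kb *Xanthomonas*-infecting
phages sampled from one orchard system over four decades, which splits into
two temporally structured clades with >99% within-clade nucleotide
similarity, ~95-96% between clades, a core of several dozen protein
families, and a handful of clade-signature clusters (a divergent terminase
large subunit appearing on both sides, plus small mobile elements such as
homing endonucleases).

# Intergenomic similarity

For genomes $A$ and $B$ the statistic is

$$\mathrm{sim}(A,B) \;=\; 100 \cdot \tfrac12
  \left( \frac{I_A}{|A|} + \frac{I_B}{|B|} \right)$$

where $I_A$ ($I_B$) is the number of positions of $A$ ($B$) covered by an
identical aligned position after merging alignment blocks. This is the
published VIRIDIC definition; identical genomes (also up to reverse
complement) score exactly 100, and `distance = 100 - similarity`.

Blocks come from an exact $k$-mer seed-and-extend scan rather than BLASTN:

* seeds: exact $k$-mers ($k = 15$) of genome $A$ located in both strands of
  $B$; seeds containing `N` or occurring more than 8 times are skipped.
* extension: along each seeded diagonal, positions are compared directly
  (`N` mismatches everything, including `N`); a block is broken wherever
  the running score (+1 match, −2 mismatch) would drop by more than the
  x-drop (20), i.e. at any mismatch run of length ≥ 10, and trimmed to its
  first/last match. Only blocks ≥ 100 bp are kept. There is no separate
  banded-gapped phase: an indel simply shifts the alignment onto a
  neighbouring diagonal, which produces a second block, and the per-position
  merging step credits each genome position once regardless of how many
  blocks cover it.
* merging: overlaps are resolved greedily by descending match count (ties
  by coordinates); a lower-priority block overlapping already-credited
  positions contributes pro-rata (`matches × uncovered/length`).

The defaults ($k$ = 15, min block 100 bp, x-drop 20, mismatch −2) are
chosen for sensitivity in the 90-100% identity range where species/genus
demarcation operates; at 10% divergence the expected spacing between
mismatches still leaves abundant 15-mer seeds. The suite verifies agreement
with a full dynamic-programming aligner (Needleman-Wunsch over 2 kb pairs)
within 2 percentage points, including an indel case, and verifies the
planted-segment construction (half-identical genomes score 50 ± edge
effects).

# Protein clustering

Proteins are compared by Smith-Waterman local alignment (BLOSUM62, gap open
11 / extend 1 — BLAST defaults), implemented in compiled code with the
identity defined as `matches / alignment columns` (gap columns count) and
per-sequence coverage as `aligned span / length`. Clustering is greedy
centroid (CD-HIT style): proteins sorted by length (desc), then genome and
gene id, are assigned to the first cluster whose representative meets the
identity threshold and the coverage rule, else found a new cluster. The
fixed sort key makes the result independent of input order, and the
greedy-vs-representative design means every cluster is a subset of one
connected component of the all-pairs threshold graph (verified against an
exhaustive oracle). Two threshold tiers mirror common practice: 70%
identity / 50% coverage for within-genus pangenomes, 50%/50% for
family-wide analyses; the coverage rule defaults to `both` (both sequences
covered), with `shorter` and `target` available.

A 4-mer prescreen skips alignments between proteins sharing no 4-mer; such
pairs cannot reach the thresholds of interest, and because the screen can
only *prevent* a join, the threshold-graph refinement property is
unaffected.

# Pangenome, signatures and ranks

The presence/absence matrix booleanizes cluster-by-genome counts. Core
clusters are those present in at least `ceiling(min_prevalence × n)`
genomes (default: all). Upset-style summaries use *exclusive*
intersections: each cluster contributes to exactly one genome-subset
signature, so counts partition the pangenome. A signature (clade-unique)
cluster must be present in *every* member of one group and *no* member of
the contrast group; per-taxon unique-core tables apply this taxon-vs-rest.

Rank demarcation is single-linkage: connected components of the similarity
graph with edges ≥ threshold (species 95, genus 70 by default, both
configurable); since the species threshold is the higher one, species
nest within genera by construction. Components are computed by a direct
graph search and cross-checked against an independent graph library in the
tests. Clade *sub*structure (below the species line) is detected from
average-linkage merge heights, cutting inside the largest gap; when no gap
reaches `min_gap` (0.5 points) the set is a single clade, which keeps
near-identical collections from being split on noise.

"Percentage of shared clusters" is reported as Jaccard (shared/union) by
default — the stricter reading — with `of_smaller` (shared/min) available
and every output labeled with its mode.

# Phylogeny

The core-genome tree is deliberately distance-based: per core cluster, one
member per genome (longest, then lexicographic gene id), pairwise distance
`1 − identity`, averaged unweighted over clusters, then classical
neighbor joining. NJ recovers additive matrices exactly (verified against
path-length oracles up to 12 taxa); negative branch lengths are clamped to
zero with the deficit moved to the sister edge so path lengths through the
parent are preserved. Midpoint rooting places the root on the longest
leaf-to-leaf path; an all-zero tree is rooted at a deterministic edge with
a warning.

Support comes from resampling core clusters with replacement (a
gene-jackknife analogue of the bootstrap — there is no site alignment in
this design, so site resampling is not available), reported per internal
bipartition of the base tree as the percentage of replicates containing it.
This is an analogue of, not a reproduction of, ML ultrafast-bootstrap
values. Congruence between trees is summarized by the unrooted
Robinson-Foulds count and the shared fraction of nontrivial bipartitions;
ties resolved into zero-length edges should be collapsed (e.g.
`ape::di2multi`) before reading topological conclusions from
near-degenerate marker trees.

Replacing the alignment+ML stack (MAFFT/trimAl/IQ-TREE) with
distances + NJ + cluster resampling keeps the pipeline dependency-light and
deterministic while preserving the quantities the analysis actually uses:
clade membership, clade support, and tree congruence.

# The synthetic community generator

`community_config()` defaults describe the study conditions: 2 clades of 9
and 6 genomes, ~45 kb each, 63 core families (150-280 aa), signature
clusters 3 (recent clade) vs 4 (older clade), sporadic short accessory
families, within-clade pairwise divergence 0.5% and between-clade 4%.

Design choices worth spelling out:

* **Rates are pairwise observables.** The mutation model substitutes each
  site independently to a uniformly chosen different base, under which two
  lineages with per-lineage substitution probabilities $a, b$ differ at a
  site with probability $a \oplus b = a + b - \tfrac43 ab$. The configured
  within/between rates are *expected pairwise divergences*; the generator
  inverts $\oplus$ to place rates on lineages. This makes the configured
  0.5%/4% directly measurable between emitted genomes (the suite checks
  every realized pairwise divergence against its expectation within 3
  binomial SDs) and yields within-clade similarity above 99% and
  between-clade similarity in the 95-96% band.
* **Signature clusters are mostly allelic.** Real clade-unique clusters in
  such communities are typically divergent variants of loci present
  everywhere (e.g. a terminase large subunit appearing in both clades'
  unique sets), not large clade-exclusive insertions. The generator plants
  `min(n_signature_families)` shared loci with one allele per clade,
  diversified by substituting 45% of interior codons at codon position 2
  (always amino-acid-changing, never stop-creating), which pushes
  between-allele amino-acid identity to ~0.55 — safely below the 0.70
  clustering threshold — at a nucleotide cost of only ~0.11 per site at
  those short loci. Any excess signature count is realized as short
  clade-exclusive families. Signature, exclusive and accessory genes are
  drawn short (90-160 aa, homing-endonuclease-like) because clade-exclusive
  content of ordinary gene length would depress between-clade nucleotide
  similarity far below what is observed in such communities (the deposited
  genomes differ by only ~600 bp in length) and below the species
  demarcation line their similarity structure must sit near.
* **Coding consistency.** Genes are `ATG` + sense codons + stop; lineage
  mutations protect the first and last codon and never create an in-frame
  stop, so the emitted proteins are exactly the table-11 translations of
  their CDS (checked file-against-file) and every selected site still
  changes, keeping divergence arithmetic exact over the mutable interior.
* **Optional stressors.** `indel_rate` adds geometric-length indels to
  intergenic spacers only (coding arithmetic stays exact);
  `discordant_marker` simulates a horizontal transfer by giving half of the
  older clade the donor clade's allele of the first core family, making
  that marker's tree discordant with the core tree. `paralog_rate`
  duplicates core genes to exercise count-vs-presence handling.

What the generator does *not* emulate: genome rearrangement and mosaicism,
recombination within genes, compositional (GC/codon-usage) structure,
pseudogenes, and sequencing artifacts. Passing the synthetic checks
therefore demonstrates correctness of the statistics and their wiring, not
robustness to assembly error or rampant mosaicism in real data.

# Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere (GenBank convention);
  translation uses table 11 with annotated alternative starts rendered as
  `M` and fuzzy codons as `X`; internal stops in conceptual translations
  are flagged, warned about, and excluded from clustering.
* Matrix TSVs serialize at fixed 4-decimal precision and round-trip
  exactly at that precision; ragged rows and non-numeric cells error with
  the offending line/cell.
* Cluster and intersection orderings are fully specified (prevalence then
  id; count then signature) so outputs are byte-reproducible.
* Ties: overlap merging by descending matches then coordinates; paralog
  choice by longest then gene id; all-zero-length trees root at a
  deterministic edge with a warning; singleton taxa report `n_pairs = 0`
  rather than erroring.
* Seeds: the generator and the resampling support both take explicit seeds
  and restore the caller's RNG state; identical seeds give byte-identical
  artifacts.

# Problem sizes

The test suite exercises the full default community (15 genomes × ~45 kb,
~1,000 proteins, 200 support replicates) once and reuses it across checks;
unit tests run on 6-genome mini-communities (~4 kb genomes, 12 core
families) whose smaller genomes make gene content a proportionally larger
signal — their species-line checks therefore use proportionally scaled
demarcation thresholds. Oracle-equivalence checks run at the sizes stated
above (trees ≤ 12 taxa, ≤ 30 proteins, 2 kb genome pairs, rank graphs ≤ 10
genomes).

# Limitations

* The seed-extend aligner is tuned for the 90-100% identity range of rank
  demarcation; at deep divergence (< ~70% identity) it undercounts relative
  to BLASTN-based VIRIDIC, so genus-level boundaries for very distant
  genomes should be read as conservative.
* Greedy centroid clustering approximates, but is not identical to,
  MMSeqs2's cascaded clustering; printed core counts can shift by a few
  clusters under different coverage modes, which is why the coverage mode
  is explicit in every run's provenance.
* Cluster-resampling support is not an ML bootstrap and should not be
  compared numerically against published ultrafast-bootstrap percentages.
* Single-linkage demarcation follows the VIRIDIC convention; it can chain
  through intermediate genomes, which is a property of the convention, not
  a bug of the implementation.
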