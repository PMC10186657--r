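---
title: "Quantifying W/Z sex chromosome differentiation with wzdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying W/Z sex chromosome differentiation with wzdiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wzdiff)
```

## The problem

In a female-heterogametic (ZW) system, the W chromosome stops recombining
with the Z over part of its length and starts to differentiate. In a young
system the signatures are subtle and heterogeneous: overall W–Z sequence
divergence may still be low while specific tracks — transposable-element
(TE) copy number, the age profile of those copies, sex-specific SNPs, and
pseudogene load — already show strong arm-specific structure. `wzdiff`
measures these tracks from assembled W and Z chromosome sequences plus
pooled female/male resequencing counts, and integrates them into a per-arm
report. The motivating system is a fish W/Z pair in which the W is a large
submetacentric (~45 Mbp) whose long arm (Wq) carries a burst of young
repeats and female-specific SNPs, while the Z is a smaller acrocentric
(~28 Mbp) that remains co-linear with the W over its whole length.

Because chromosome-scale sex-chromosome assemblies plus pool-seq data are
rarely at hand, the package ships a deterministic synthetic Z/W generator
with complete ground truth, so the entire pipeline is testable offline.
All internal coordinates are 0-based half-open; 1-based coordinates occur
only at file boundaries (pooled-count TSV input, human-readable output).

## Windowed divergence

`anchor_align()` aligns two co-linear chromosomes by chaining k-mers that
occur exactly once in each sequence (longest-increasing-subsequence
chaining), closing inter-anchor segments with a banded affine
Needleman–Wunsch, and breaking blocks at larger unaligned stretches (TE
insertions, the centromeric N-gap). It is a deliberate substitute for an
external whole-genome aligner at desk scale; rearranged chromosomes are
out of scope and should be imported as PAF (`read_alignment()`, extended
`=`/`X` CIGAR required — plain `M` is rejected because mismatches would
be indistinguishable).

`block_changes()` implements the counting rule: every mismatched base is
one change (a SNP), and every insertion or deletion run is one change
regardless of length, anchored at the reference position of its left
edge. `window_divergence()` tiles 10-kb windows from position 0 and
reports `100 * changes / denominator`.

Numerical choices worth knowing:

* **"Sliding" windows are non-overlapping tiles by default** (`step =
  window`). Quartile summaries over windows are most interpretable for a
  tiling; an overlapping step is available via `step`.
* **The denominator is the window size by default** (a literal
  "percentage of mutations per 10-kb window"); `aligned_bases` is offered
  because handling of unaligned stretches is a genuine ambiguity in this
  kind of statistic.
* **Masking, not zeroing**: windows whose aligned fraction is below
  `min_aligned_frac = 0.5` get `pct = NA`. Without this, an assembly
  N-gap would read as a stretch of spurious 0% divergence.
* Positions where either sequence carries `N` are excluded from both the
  change and the aligned-base counts.
* Quartiles use linear interpolation (R's type 7), a concrete testable
  convention.
* An indel spanning several windows is counted once, in the window of its
  leftmost reference base.

The affine gap scores of the internal aligner (match +1, mismatch −1, gap
open −3, extend −0.5) are chosen so that a compensating insertion +
deletion pair can never outscore plain substitution columns: diverged but
co-linear segments therefore stay gap-free, and no phantom indel changes
(or phantom frameshifts, below) are introduced.

## TE age landscape

For each repeat copy aligned to its family consensus,
`count_substitutions()` tallies transition (`p`) and transversion (`q`)
proportions over aligned, non-gap, non-N columns, and `kimura2p()`
computes the Kimura 2-parameter distance

\[ K = -\tfrac{1}{2}\,\ln\bigl((1-2p-q)\sqrt{1-2q}\bigr), \]

reported on the ×100 scale for thresholding. A copy is *young* iff
`K < 1` (strict). The CpG adjustment follows the convention of
RepeatMasker's CpG-aware divergence: a transition whose consensus
position lies in a CpG dinucleotide is down-weighted to 1/10 (CpG sites
are hypermutable, so unadjusted counts make young copies look old), and
when both positions of one CpG carry transitions the pair counts once, in
full. `cpg_mode = "off"` is provided for sensitivity analysis; the
adjusted distance is never larger than the unadjusted one, which is
asserted as a property test.

Outside the Kimura domain (`1-2p-q <= 0` or `1-2q <= 0`) the distance is
saturated: the copy is flagged (`saturated = TRUE`, `kimura = NA`) rather
than scored. Copies are assigned to regions by interval midpoint, a
deterministic rule for copies straddling the arm boundary.

Note that "young" is a threshold on a *realized* distance: the generator
draws each copy's substitutions binomially around its age-component mean,
so a small tail of young-component copies can cross K = 1 on short
consensi. Recovery tests therefore compare fractions, not individual
labels.

## Gene decay

`project_genes()` maps CDS queries onto a chromosome by exact k-mer
seeding on both strands, seed clustering, and refinement with the anchor
aligner under a cost-bounded band (long-but-thin gaps — introns against a
co-linear CDS — are still closed). Coverage and identity are computed at
the nucleotide level from the refined alignment. Hits are filtered with
strict thresholds (`coverage > 0.35`, `identity > 0.50`), and overlapping
hits are resolved per locus: reciprocal >50% overlaps keep the best score;
a hit of the *same* query mostly contained in a better-scoring hit is
discarded as a redundant fragment (distinct loci of one query survive —
that is what captures duplications).

The pseudogene call is made from the coding alignment:

* Target-only gap runs separated by at most 12 aligned columns are merged
  into one *gap cluster* (an aligner places splice boundaries imperfectly;
  a few exon bases matching intron sequence by chance would otherwise
  split one intron into "intron + small gap" and fake a frameshift).
  Clusters totalling ≥ `min_intron` (40 bp) are introns and excluded from
  the spliced projection; smaller clusters and query-only gaps are coding
  gaps, and any such gap with length not divisible by 3 flags a
  **frameshift**.
* The **premature stop** scan works in query codon coordinates: a codon
  is translated only when all three of its query positions are aligned,
  so alignment noise can never shift the reading frame of downstream
  codons. Three columns on each side of every intron are blanked before
  the scan (boundary jitter), and the final aligned codon — the gene's
  own terminator — is excluded. Frameshift takes precedence when both
  signals are present.

**Known limitation.** A 1–2 bp lesion immediately adjacent to an
exon/intron boundary can be absorbed into the intron gap by any spliced
aligner — the gap merely changes length, and intron lengths are
arbitrary — so frameshift recovery is near-perfect rather than perfect
(≈97% per-gene agreement with generator truth at 5% divergence in the
acceptance run). Likewise a premature stop falling in the blanked
boundary columns can be missed. These ambiguities are inherent to spliced
projection, not to this implementation.

Two open design points were resolved as follows and are exposed as
options rather than hidden: identity is **nucleotide-level** (the
alternative, protein-level identity, depends on an alignment model the
source analysis does not specify; at ≥95% nucleotide identity the two
disagree only marginally), and the **H-score**, which is named but never
defined where it is used, is defined here as
`H = 100 * S(a,b) / min(S(a,a), S(b,b))` with `S` a local alignment score
(match +2, mismatch −3, gap open 5, extend 2). This makes `H` symmetric,
100 on self-comparison, and near 0 for unrelated sequences; the
duplication threshold `H > 90` is kept. `cluster_duplicates()` reports,
per source gene, target loci with `H > 90` when at least two copies
exist, with per-arm copy counts.

## Sex-specific SNPs

The pooled caller is fully parameterized (`snp_call_params()`) because
the upstream pool-seq pipeline it stands in for is not described in
detail anywhere usable: defaults are minimum depth 10 in **both** pools
(a site uncallable in either pool can never be declared sex-specific),
≥3 alternate reads and ≥10% alternate frequency in the carrier pool, and
**zero** alternate reads tolerated in the other pool. At most one call is
made per site: the qualifying allele with the highest carrier-pool
frequency wins, ties broken lexicographically. The calls are symmetric
under swapping pool and sex labels, which is tested as a property.
`region_snp_enrichment()` reports density folds (calls per Mbp) with a
conditional-binomial Poisson rate-ratio interval; a zero-count
denominator yields an infinite fold with a finite lower bound.

## Karyotype arithmetic and the report

`find_n_gaps()` extracts maximal N-runs (≥1 kb by default).
`centromere_candidates()` converts a cytogenetic arm-length ratio
(`arm_fraction ± fraction_sd` of total length) into the two mirror-image
candidate intervals `[(f−sd)L, (f+sd)L]` and `[(1−f−sd)L, (1−f+sd)L]` —
both are always reported because the orientation of an assembly relative
to the metaphase chromosome is unknowable from sequence alone. With
L = 45 Mbp, f = 0.596, sd = 0.022 these are 25.8–27.8 and 17.2–19.2 Mbp.
Mbp values are rounded half-up to one decimal in human-readable output;
JSON carries full precision.

`partition_arms()` is gap-delimited: long arm `[0, gap.start)`, gap,
short arm `[gap.end, L)`, with the long arm at the sequence start by
convention and a `flip` flag for the opposite orientation. Any published
Mbp constants for arm boundaries are configuration, not code constants,
because gap-adjacent boundaries are reported inconsistently across
sources. `build_report()` rolls every track up per arm; missing tracks
are marked `"absent"` (never zero), config and tool versions are
embedded, and regeneration from identical inputs is byte-identical.

## What the generator emulates — and what it does not

`simulate_pair()` states a 1/10-scale world by default:

| parameter | default | meaning |
|---|---|---|
| `z_length` | 2.8 Mb | Z length (1/10 of ~28 Mbp) |
| `w_long_frac` | 0.5 | fraction of Z homologous to the W long arm |
| `gap_frac` | 3/28 | centromeric N-gap, as a fraction of `z_length` (300 kb) |
| `base_divergence` | 0.009 | per-base W–Z substitution probability (~0.9%) |
| `indel_rate` | 5e-4 | indel events per base; lengths 1 + Geom(0.5) |
| `te_burst_rate_long` / `te_rate_short` | 600 / 60 per Mbp | TE insertions per arm; the 10× contrast and mean copy length (~1.65 kb) expand the long arm to ~2× its Z homolog, matching the real arm proportions |
| `te_age_young_frac_long` / `short` | 0.01 / 0.0039 | young-component fractions (≈1% vs ≈0.39%) |
| `kimura_young_mean` / `kimura_old_mean` | 0.005 / 0.15 | per-copy divergence of the two age components |
| `n_genes` | 200 | planted multi-exon genes, split between arms by homolog length |
| `pseudo_frac_long` / `short` / `autosome` | 0.209 / 0.163 / 0.125 | planted pseudogene fractions |
| `snp_rate_w_long` / `snp_rate_background` | 1.5 / 0.1 per kb | female-specific SNP planting rates (15-fold long-arm excess) |
| `pool_depth` | 40 | mean Poisson depth per pool |

A single RNG stream seeded from the config drives every draw in
documented order (Z sequence, TE consensuses, then per arm:
substitutions, indels, TEs, genes; finally SNP sites), so identical seeds
give byte-identical FASTA output.

Deliberate simplifications, each of which limits what a green test
establishes:

* **Planted gene copies diverge codon-aware and stop-free**: substitutions
  never create an in-frame stop, and intron GT…AG ends are never mutated
  (as real splice sites, they are conserved). Without this, 5% random
  divergence would plant spurious "premature stop" lesions and truth
  labels would be meaningless. Consequently, recovery tests validate the
  *caller*, not robustness to stop-codon-generating neutral divergence.
* **Micro-exons are excluded** (exon boundaries on a 30-nt grid): exons
  below the seed size would be unmappable by construction for any aligner.
* The female pool draws a planted alternate allele at expected frequency
  **0.5** — a heterogametic ZW female carries one W allele against one Z
  allele — configurable via `female_alt_freq`. The male pool sees it only
  through sequencing error. Read mapping, mapping bias and paralog
  collapse are not modeled.
* TE copies are full-length consensus copies, substitution-mutated only:
  no nesting, fragmentation, or indel divergence. An indel is one truth
  event regardless of length, mirroring the divergence counting rule.
* No recombination/coalescent structure; homology is strictly co-linear.

## Acceptance surface

`tests/testthat/test-acceptance.R` implements six criteria: exact
in-source arithmetic (pseudogene percentages 20.9%/16.3%, young-TE
percentages 1%/0.39%, the 8.4% long-arm excess over the 12.5% autosome
reference, the centromere intervals, the 17 Mbp W–Z size difference);
divergence recovery at 1 Mb (0.93 ± 0.05); a 1e-10 closed-form Kimura
check plus the CpG inequality on 1,000 random alignments; pseudogene
recovery with 200 planted genes at 5% divergence (fraction within 3
binomial SD, ≥95% per-gene lesion agreement); perfect sex-SNP recall at
zero error with the 15× enrichment inside a 99.9% Poisson interval (the
3-SD convention used throughout); and the conservation/determinism
property suite. `scripts/acceptance.R` recomputes the reportable targets
from scratch against the installed package.
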