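---
title: "Methods: census, expression and chromatin analysis of KRAB-ZFP genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: census, expression and chromatin analysis of KRAB-ZFP genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(krabkit)
```

KRAB zinc-finger proteins (KRAB-ZFPs) are the largest transcription-factor
family in mouse and human. Each combines an N-terminal KRAB repression
module, which recruits the corepressor KAP1/TRIM28 and with it H3K9me3
heterochromatin machinery, with a C-terminal array of C2H2 zinc fingers
that reads DNA sequence. A minority of family members (KRAB-only, KRAB-O)
lack fingers altogether. This vignette explains, stage by stage, the models
and conventions the package implements, the parameters that matter, and
what the synthetic-data generators do and do not emulate.

## Domain census

A gene enters the census when an upstream annotation records a KRAB domain
in one of its protein products; the package deliberately does not
re-implement profile-HMM domain detection, because family-scale analyses
start after domain identification and annotation tables are the stable,
shareable artifact. For each annotated gene the longest protein isoform is
selected (ties broken by the lexicographically smallest transcript id, a
convention chosen purely for determinism) and scanned for C2H2 fingers
with the pattern

```
C - X(2-4) - C - X(12) - H - X(3-5) - H
```

i.e. substrings of 21–25 residues. The two variable gaps make the pattern
ambiguous; `extract_zinc_fingers()` resolves it as *leftmost,
shortest-match, non-overlapping* scanning (the scan resumes after each
accepted match). This is the minimal-finger reading: it never merges two
fingers into one sprawling match, and it makes counts reproducible. `X` is
accepted in sequences but never satisfies a C/H anchor position. A gene
with at least one finger is a KRAB-ZFP; with none, KRAB-O.

The KRAB D5/V6 check reads positions 5 and 6 (1-based) of the annotated
domain substring — the alignment convention under which the
aspartate–valine dipeptide required for KAP1 recruitment sits at positions
5 and 6. Ssx-type KRAB-O domains characteristically lose V6, and the
census carries both flags so that such families are visible.

## Genomic clusters

A cluster is at least two family genes within 200 kb of each other.
`find_clusters()` interprets "within 200 kb" as the *edge-to-edge gap
between neighbouring genes* with single-linkage chaining, not an all-pairs
constraint: large clusters (40+ genes) span far more than 200 kb in total,
which only the chaining reading permits. Genes are sorted by start within
each chromosome and chained while `next_start - running_max_end <= max_gap`
(the running maximum end handles nested and overlapping genes, making the
result exactly the transitive closure of the pairwise gap relation, which
the test suite verifies against a brute-force oracle). Overlapping genes
have gap 0; strand is ignored; cluster ids count up through natural
chromosome order (1, 2, …, 10, …, X) then leftmost position; singletons
get id 0. Whether the published convention measured TSS-to-TSS or
edge-to-edge distance is not stated; edge-to-edge is recorded here as the
package's convention and the cluster tests exercise it.

## Orthology from zinc-finger arrays

Cross-species comparison uses only the DNA-reading part of each protein:
the concatenation of its fingers in order, spacers excluded
(`build_zf_array()`). KRAB-O proteins have nothing to align and are
excluded. `percent_homology()` aligns two arrays globally (end-to-end)
and reports `100 * identical_columns / alignment_columns`, gaps included
in the denominator — so arrays with different finger counts are penalized,
which is the behaviour that makes a conserved-core-but-extra-fingers pair
(the ZFP57 situation) fall below the cut-off. Scoring is match +1,
mismatch −1, affine gaps costing `open (5) + length × extend (1)`; the
original analysis used a progressive multiple-alignment tool whose scoring
is not bit-reproducible, so the scoring here is explicit, configurable and
recorded, and the 117-pair published count is treated as a soft target
only. `call_orthologs()` keeps *all* cross-species pairs strictly above
the threshold (default 70%), including one-to-many matches, because
without functional data the "true" ortholog among several candidates
cannot be designated.

## nCounter expression pipeline

Digital hybridization counts need no amplification correction, so the
model is additive background plus multiplicative scale:

1. **Background**: per assay, subtract the geometric mean of the negative
   control probes; anything at or below zero becomes 0.1 (the floor keeps
   later log and ratio arithmetic defined). Zero negative counts are
   replaced by 1 inside the geometric mean — except when every negative in
   an assay is zero, in which case the background is 0.
2. **geNorm stability**: for housekeeping genes j, k, the pairwise
   variation V~jk~ is the standard deviation across assays of
   log2(x~j~/x~k~); M~j~ is the mean of V~jk~ over partners k. M is
   scale-free (multiplying an assay's counts through cancels in the
   ratio), which the tests assert numerically. Genes with M < 0.5 are
   selected as references (one-pass rule, the applied criterion); the
   classical iterative-exclusion ranking is also computed for QC. With
   fewer than two genes under the cut-off the two most stable are used,
   with a warning.
3. **Normalization factors**: per assay, the geometric mean of the
   selected references, rescaled to geometric mean 1 across assays so
   normalization changes no global scale. All counts are divided by their
   assay's factor.
4. **Averaging and relative values**: replicate assays are averaged per
   cell type (arithmetic mean), then each gene's profile is divided by its
   geometric mean over cell types and log2-transformed; rows of the
   relative matrix sum to zero by construction. Averaging precedes the
   relative-log transform (the order is ambiguous in prose descriptions of
   such pipelines; this order is the package's recorded choice).
   A gene is *expressed* when its averaged count exceeds θ = 99 in at
   least one cell type — strictly greater, so 99.0 itself is silent.
5. **Correlation and clustering**: Pearson correlation between cell types
   on relative log2 values; average-linkage clustering on Euclidean
   distances.
6. **Differential calls**: assays are pooled into four stage groups
   (2i+LIF pluripotent; BMP4/FCS+LIF pluripotent; EpiSC/embryoid-body;
   committed). The main contrast is pluripotent (G1∪G2) vs the rest with
   a two-sided Mann–Whitney U per gene and Benjamini–Hochberg adjustment
   across genes. The published description says only "non-parametric
   analysis"; Mann–Whitney is the default here and a Kruskal–Wallis
   alternative is exposed. Calls require adjusted p ≤ α *and* a group-mean
   fold change ≥ 2 (means floored at 0.1), with direction deciding
   pluripotency- vs non-pluripotent-associated. *Housekeeping-like* means
   no significant pairwise group difference and maximum between-group fold
   < 2. Both α = 0.05 and the stricter 0.01 preset are exposed, since the
   source description uses both thresholds in different places.

## ChIP interval statistics

All coordinates are 0-based half-open throughout. The promoter is
TSS −3.5 kb/+500 bp, strand-aware (assumed strand-aware for minus-strand
genes, which the description leaves implicit); the extended window is the
gene body ±3.5 kb. For meta-gene profiles the extended window is divided
into 8 near-equal bins (remainder spread from the 5′ side; bin order
reversed on the minus strand so bin 1 is always 5′-most); a bin is "hit"
by a mark if any enriched region overlaps it by ≥1 bp. The published
figure legend is ambiguous about whether the 8 bins cover the body only
or body plus flanks; the default here is body plus flanks, with
`body_only = TRUE` implementing the alternative. Enrichment is any
overlap, with no minimum fraction.

Nearest-ERV distances drop ERVs shorter than 500 bp, then take the
minimal edge-to-edge gap between the gene body and any retained ERV on
the same chromosome (0 on overlap; genes on ERV-free chromosomes are
excluded). Group comparisons use a two-sided Wilcoxon rank-sum test:
exact enumeration when the pooled sample is ≤12 without ties, otherwise
the normal approximation with tie and continuity correction; when every
pooled value is identical the p-value is defined as 1. When several marks
are tested, BH adjustment applies across marks.

## qPCR quantification

`relative_quantity()` implements ΔΔCT: replicate CTs are averaged per
(sample, gene); ΔCT is target CT minus the *arithmetic mean* of the
normalizer CTs (equivalent to the geometric mean of normalizer
quantities — the natural aggregation on the CT scale, not stated
explicitly in the source description); ΔΔCT subtracts the reference
sample's ΔCT; RQ = 2^−ΔΔCT, so the reference is exactly 1. Per-sample CT
offsets (loading differences) cancel identically, which the tests assert.

## What the synthetic generators emulate — and what they do not

The generators produce inputs at the study's stated conditions with
ground truth serialized alongside:

- `sim_proteome()` (default 357 genes, 36 KRAB-only, finger counts with
  mean ≈ 11.7 truncated to 1–33 via a shifted negative binomial — the
  family's size, composition and mean array length): planted KRAB-like
  consensus (D5/V6 intact, or V6 mutated for Ssx-style domains) plus
  pattern-true fingers separated by linkers drawn from an alphabet without
  C or H, so planted instances are provably the only matches. Real
  proteins contain C and H outside fingers, degenerate fingers, and
  KRAB-B boxes; recovery being exact on synthetic data therefore shows
  scanner correctness, not that real annotations would be reproduced.
- `sim_loci()` (default clusters of 2, 5 and 41 genes plus 10 singletons
  on mouse-scale chromosomes): within-cluster gaps ≤ 200 kb, entities
  separated by > 200 kb, so the planted partition is the unique correct
  answer. Real cluster structure (50 clusters over 21 chromosomes) is
  not emulated in full, only its defining geometry.
- `sim_counts()` (default 232 targets, 21 housekeeping, 8 negatives;
  10 cell types × 3 replicates spanning the four stage groups — a
  deliberate scale-down of the study's 53 assays chosen to keep replicate
  structure per group while staying small; planted 4-fold effects on
  10 + 10 genes at CV 10%): counts are
  `round(lognormal(baseline + effect, cv)) + Poisson(background)` —
  positive, overdispersed, invertible in tests. Baselines are uniform on
  log2 4–13 so that roughly 70% of targets clear the 99-count threshold,
  matching the observed expressed fraction. The model has no
  probe-affinity differences, no cartridge batch effects and no
  correlation between genes, so it validates the arithmetic of the
  pipeline, not its robustness to platform artifacts.
- `sim_chip()`: marks placed in chosen bins (configurable 5′→3′ bias),
  ERVs planted at known gaps with a near group and a far group
  (default shift 5 kb) and a configurable fraction of sub-500 bp decoys
  that the length filter must remove. Planted gaps are exact for
  well-separated genes; clustered genes can sit nearer a neighbour's ERV
  than their own, which is why the recovery tests use singleton layouts.
- `sim_qpcr()`: CT tables with per-sample offsets that ΔCT must cancel
  and planted log2 fold changes, measurement noise 0.05 cycles.

Each generator draws from its own RNG stream derived from the master seed
and a stable label, so outputs are byte-identical for identical
(seed, config) and adding one generator never perturbs another.

## Numerical choices and degenerate inputs

- Geometric means require positive values; the 0.1 background floor
  guarantees this downstream. Zero negatives are handled as above.
- Normalization factors are validated positive; geometric-mean-1 scaling
  is asserted to 1e-9.
- Equal-length isoform ties, equal-score alignments and bin-remainder
  placement are all resolved by fixed documented conventions
  (lexicographic transcript id; canonical argument order before
  alignment, which also enforces exact symmetry of percent homology;
  remainder bins from the 5′ side).
- Zero-variance samples make Pearson correlation undefined and raise an
  error naming the sample rather than propagating NaN.
- Genes with a group holding fewer than two replicate values are skipped
  by the differential caller with a warning.

## Problem sizes

The shipped tests and the acceptance script run the census at the full
family scale (357 genes), clusters at 58 genes, orthology on 20 four-finger
arrays, the count pipeline at 232 + 21 + 8 probes × 30 assays (null
simulations at 500–1000 genes), ERV statistics at 200 genes, and
alignment-oracle comparisons on arrays up to 12 residues. These sizes were
chosen so every property that admits an exact oracle is checked exactly
and every stochastic property has comfortable power.

## Known limitations

- The census is annotation-driven: genes whose KRAB domain is absent from
  the input annotation are invisible, exactly as in any
  database-filter-based census.
- Percent homology depends on alignment scoring; published pair counts
  from other tools are reproducible only approximately.
- The differential caller's published comparison counts (9/8/12
  stage-specific genes) depend on an unspecified test and correction and
  are not asserted.
- Interval statistics are presence/absence; read-depth (signal-level)
  meta-gene curves are out of scope.
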