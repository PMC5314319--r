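---
title: "Methods: integrative analysis of UV-induced gene dysregulation"
author: "uvomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative analysis of UV-induced gene dysregulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uvomics)
```

# Scope and model

Acute ultraviolet irradiation perturbs skin cells on three coupled
levels: it mutates DNA (modestly), redistributes the active-chromatin
mark H3K27ac (extensively), and dysregulates transcription (extensively).
`uvomics` implements the quantitative machinery needed to dissect those
layers jointly from standard assay outputs — scored H3K27ac peak
intervals, a gene annotation, normalized expression values, somatic SNV
calls, and an shRNA depletion screen — and ships seeded generators that
emulate each input with planted effects, so every stage is testable
end-to-end without external data.

All interval work is done on `GRanges` (1-based, closed coordinates, the
Bioconductor convention); BED input/output is converted at the file
boundary, GFF3 and VCF are natively 1-based. Gap distances treat
overlapping or abutting intervals as distance 0, so the same arithmetic
serves peak-to-gene assignment, promoter exclusion, enhancer stitching
and SE–gene association.

# Differential H3K27 acetylation (DHA)

A gene's acetylation level in a sample is the mean signal of the peaks
assigned to it; a peak is assigned to every gene whose body lies within
10 kb (`window`). The UV/control fold change uses a pseudocount of 1 on
both means, which defines the ratio when a gene has peaks in only one
condition, and classifies genes by strict thresholds: `up` if FC > 2,
`down` if FC < 0.5, `none` otherwise — a gene at exactly the cutoff is
unclassified. The genome-wide trend is summarised by the least-squares
slope *through the origin* of UV on control tag totals over the union of
both samples' peak intervals ("merged peak regions"); a slope below 1 is
a net loss of acetylation. The through-origin form makes a uniform
scaling of one sample map exactly onto the slope, which is the quantity
the trend is meant to capture.

# Super-enhancer identification

Super enhancers are identified in the rank-ordering style: peaks within
2.5 kb of any TSS are removed (promoter exclusion; the window is closed,
so a width of 0 still covers the TSS base), the remaining constituent
enhancers are stitched whenever consecutive peaks are separated by at
most 12.5 kb, and stitched enhancers are ranked by their summed
constituent signal. The cutoff is the curve's transition point: after
min–max scaling rank (x) and signal (y) to the unit square, the cutoff
index maximises the depth below the diagonal, `x − y`. On a convex
hockey-stick curve this is exactly the point where the tangent slope
passes 1, but unlike a finite-difference tangent criterion it is
well-defined on any curve, exact, and oracle-checkable by exhaustive
scan. Ties go to the smallest index; a curve with no point below the
diagonal (e.g. perfectly linear) is flagged degenerate; a constant
vector has no transition point and is an error. Membership is strict
(`total_signal > cutoff_signal`), so the transition-point enhancer
itself is not a super enhancer.

Two SE sets are compared by interval overlap: an SE is "common" when it
overlaps an SE of the other sample by at least 1 bp (configurable).
Because one broad SE can span several in the other sample, the common
counts are reported per set and need not agree. Genes are associated
with an SE when the gene body lies within 25 kb of the SE boundary.

# Expression integration

Differential expression uses the same pseudocount-and-strict-threshold
fold-change rule (FC > 2 / < 0.5) on normalized expression values;
significance testing of the underlying counts is deliberately out of
scope (an externally computed p-value column is carried through if
present), because a single-donor two-condition design leaves no
replicate structure to model. For integration, genes are binned by
acetylation log2FC — above +1, below −1, or in between — with boundary
values falling in the middle bin, and the expression log2FC of each
extreme bin is compared against the middle bin with Student's
(pooled-variance) two-sample t-test, the convention for comparing group
means of log fold changes; Welch's form is available by flag. The 3×3
concordance matrix of expression class against acetylation class
summarises co-directional (up/up, down/down) and inverse (up/down,
down/up) regulation.

# Enrichment statistics

Gene-set enrichment in a ranked list uses the classical unweighted
Kolmogorov–Smirnov statistic: the signed deviation of maximal magnitude
between the running fraction of set members and non-members down the
list (positive = concentrated at the top). A weighted running-sum
variant exists behind a flag but is off by default. Significance comes
from gene-label shuffling: the score is recomputed for `n_perm` random
same-size sets and `p = (1 + #{null ≥ observed}) / (n_perm + 1)`; the
add-one rule keeps p strictly positive and the estimator valid. Every
stochastic call takes an explicit seed and echoes it in its output.
Pathway over-representation uses the hypergeometric upper tail
P(X ≥ k) over a stated gene universe with Bonferroni adjustment across
the pathways tested.

# Variant profiling

SNVs are read from minimal VCF (or an equivalent TSV), with non-SNV
records skipped and counted. Variants with fewer than 10 reads are
discarded (depth exactly 10 is kept). Two timepoint sets intersect on
the full identity (chrom, pos, ref, alt) — the same position with a
different alternate allele is a different variant. Each variant gets
exactly one genomic category with precedence
exon > 5′-UTR > 3′-UTR > intron > 1 kb upstream > 1 kb downstream >
intergenic, where "exon" means protein-coding exonic sequence outside
the UTRs and the flanks are measured strand-aware from the gene-body
ends. The substitution spectrum folds purine-rooted changes onto their
pyrimidine representation, so C>T and G>A jointly form the UV-signature
class.

# shRNA essentiality

The depletion-score pipeline follows the Achilles-style recipe. Raw
counts, if given, become `log2(CPM) + 1` (zero counts offset by +0.5,
flagged); scores are then centered per sample on the median of the
negative-control shRNAs. The within-gene consistency filter compares the
absolute pairwise differences among a gene's shRNAs (pooled over
samples) against absolute differences of random shRNA pairs (the null;
subsampled to at most 1e5 seeded draws, enumerated exactly when smaller)
with a one-sided rank-sum test — a gene passes at p < 0.1 when its
shRNAs behave more similarly than random pairs. Passing genes collapse
to a per-line median, and a one-sided rank-sum test flags genes whose
gene-level score is lower in skin than non-skin lines at p < 0.05 (a
flag additionally requires the skin median to actually be the lower
one). For small line panels the rank-sum p is computed by exact
enumeration of all C(n+m, n) label assignments on midranks, which stays
valid under ties; large samples use the normal approximation (verified
to match `stats::wilcox.test` to full precision). No multiple-testing
adjustment is applied, matching the raw 0.1/0.05 thresholds the
procedure is defined with.

Two statistical honesty notes. First, with 4 skin and 8 non-skin lines
the exact rank-sum test is discrete: its largest attainable level below
0.05 is 18/495 ≈ 0.036, so a fully null screen is flagged at ~3.6%, not
5% — the tests assert against the enumerated level. Second, the
within-gene pairwise differences are mutually dependent (6 pairs from 4
shRNAs share values), which makes the consistency test anticonservative:
under a fully exchangeable null screen the nominal 0.1 threshold passes
roughly 15% of genes. The filter should therefore be read as an
enrichment step for coherent shRNA families rather than a calibrated
hypothesis test; the alternative "pooled values" null (which calibrates
at 0.10 but tests location rather than coherence) is available via
`null_type = "values"`.

# The synthetic study

The generators encode the study conditions the pipeline is designed for,
and their defaults are fixed once:

* **Genome**: three chromosomes totalling 16.5 Mb carrying 200
  non-overlapping genes (2–6 kb, three exons, terminal UTRs, random
  strand). Consecutive genes are separated by 13–18 kb — above the
  12.5 kb stitch distance, so gene-proximal peaks never chain across
  genes — with a 25% admixture of 52–70 kb gaps that host distal
  enhancers close enough to genes for the 25 kb SE-association window
  to be exercised. The genome is larger than strictly needed for the
  gene count because enhancer placement demands isolation: background
  enhancers sit on an 18 kb grid with >17.5 kb clearance from gene
  bodies, guaranteeing that no background or planted enhancer can
  stitch with promoter peaks and that planted clusters are the only
  high-aggregate stitched enhancers by construction. Generation is
  sub-second.
* **H3K27ac**: every gene carries promoter-proximal peaks (they drive
  the gene-level DHA calls and are excluded from SE calling by the
  promoter filter, keeping the DHA and SE plantings orthogonal); 500
  background enhancers draw log-normal signal (sdlog 0.6 around a base
  of 10) with a 5% boosted tail, producing the hockey-stick rank curve;
  20 planted clusters of 4 peaks within the stitch distance carry 50×
  background signal. The UV sample reuses the same intervals scaled by
  a global multiplier (0.7: net loss), with planted DHA genes scaled
  ±4-fold, 5 clusters collapsed to background scale (a lost SE must
  fall to background, not to a few percent of cluster scale, or its
  residual still out-ranks the background tail) and 2 background-level
  loci boosted to cluster scale only after UV — a net SE loss of 3.
* **Expression**: log-normal baseline (median 100), 20+20 planted 8-fold
  DGE genes disjoint from the DHA genes, full DHA–DGE coupling by
  default (+2 log2 units on coupled genes), log2-normal noise with
  σ = 0.5.
* **Variants**: two sets of 463 and 417 SNVs sharing 75, positions drawn
  inside the exact feature space of their planted category (40% intron,
  28% intergenic, 13% exon, the rest UTRs and flanks, or an exact
  per-category quota for the shared set), substitution classes drawn
  with 60% weight on the UV-signature class, depths uniform on 10–100.
* **Screen**: 500 genes × 4 shRNAs plus 100 negative controls across 4
  skin and 8 non-skin lines; per-gene baselines N(0, 1), per-shRNA
  noise N(0, 0.5), 10 planted genes shifted −3 in skin lines only. The
  control count matters: control-median centering subtracts a *shared*
  per-sample offset, and with too few controls that offset's noise
  moves all genes of a sample coherently and destroys the null
  calibration of the lineage test; 100 controls (the scale of the
  luciferase/GFP/RFP/LacZ families in Achilles-style screens) keep the
  centering precise.

What the generators deliberately do not emulate: read-level data (peak
signal is consumed as given, as the pipeline defines), overlapping or
nested gene models, trinucleotide mutation context, copy-number effects
on screen scores, and batch structure across cell lines. Passing the
planted-recovery tests therefore demonstrates the correctness of the
computations under clean planted effects, not robustness to every
artefact of real assays.

# Numerical and design choices

* Strictness at thresholds (FC exactly 2 → `none`; log2FC exactly ±1 →
  middle bin) is uniform and tested.
* The transition-point cutoff resolves depth ties to the smallest index
  and warns on degenerate (never-below-diagonal) curves.
* Random-number use is always behind an explicit seed argument
  (generators, permutation tests, null subsampling); two runs with the
  same inputs and seed are identical.
* Problem sizes in the tests and the acceptance script (200-gene
  genome, ≤1,000 peaks per sample, 500-gene screens, 1,000-vector
  oracle sweeps, 199–1,000 permutations) were chosen so the whole suite
  exercises every stage at full fidelity in a couple of minutes on one
  CPU.
* `run_uv_pipeline()` plus the numbered scripts under `analysis/` are
  the orchestration surface; each stage is equally callable on its own.

# Known limitations

Headline counts from any real experiment (numbers of DHA genes or SEs)
depend on sequencing depth, peak calling and normalization upstream of
this package and are not reproducible from synthetic data; the package
instead validates the machinery by construction (oracle equivalence,
planted-effect recovery, calibration under null generators). The KS
enrichment p-value is one-sided toward top-of-list concentration;
rankings must be oriented by the caller. The consistency filter's
anticonservativeness under dependence is documented above rather than
corrected, to keep the published procedure's semantics.
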