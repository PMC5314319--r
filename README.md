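# uvomics

Integrative analysis of UV-induced epigenomic, transcriptomic and
genetic dysregulation in skin cells.

Acute ultraviolet irradiation redistributes the active-enhancer mark
H3K27ac genome-wide, dysregulates thousands of transcripts, and leaves a
comparatively modest somatic mutation footprint. Connecting those layers
requires a chain of specific computations, and `uvomics` implements that
chain as a tested R package:

* **Differential H3K27 acetylation (DHA)** — per gene, the fold change
  of the mean signal of H3K27ac peaks within 10 kb of the gene body
  (pseudocount 1), classified by strict cutoffs FC > 2 / FC < 0.5, plus
  the genome-wide trend as the through-origin slope of UV on control tag
  totals over merged peak regions (slope < 1 ⇔ net loss).
* **Super enhancers (SEs)** — promoter-peak exclusion (TSS ± 2.5 kb),
  12.5 kb stitching of constituent enhancers, rank-ordering by total
  signal, and a cutoff at the transition point of the min–max-scaled
  rank/signal curve: the index maximising the depth below the diagonal,
  x̂ − ŷ (where the tangent slope of a convex curve passes 1). SEs are
  compared across samples by overlap and associated with genes within
  25 kb.
* **Expression integration** — fold-change DGE classification, three-way
  binning of acetylation log2FC at ±1, Student's t-test of expression
  log2FC in each extreme acetylation bin against the middle bin, and the
  3×3 expression-by-acetylation concordance matrix.
* **Enrichment** — unweighted Kolmogorov–Smirnov gene-set statistic with
  gene-shuffling permutation p-values (add-one rule), and hypergeometric
  pathway over-representation P(X ≥ k) with Bonferroni adjustment.
* **Variants** — minimal VCF/TSV input, depth ≥ 10 filter, timepoint
  intersection on (chrom, pos, ref, alt), single-category genomic
  classification (exon > UTRs > intron > 1 kb flanks > intergenic), and
  the strand-collapsed substitution spectrum whose C>T/G>A class is the
  UV signature.
* **Essentiality** — an Achilles-style shRNA depletion-score pipeline:
  log2(CPM)+1 normalization, negative-control median centering,
  within-gene consistency filter against a pairwise-difference null
  (rank-sum, p < 0.1), per-line median collapse, and a one-sided
  rank-sum test for lower scores in skin than non-skin lines (p < 0.05),
  exact by enumeration for small line panels.
* **Synthetic data** — seeded generators for every input with planted
  ground truth (SE clusters, DHA/DGE genes with configurable coupling,
  variant composition and overlap, skin-essential genes), so each caller
  is validated by parameter recovery.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data; `Rscript analysis/01_simulate.R` then `02`…`06` reproduces it
step by step. The same flow in a session:

```r
library(uvomics)

cfg  <- simulation_config(seed = 1)
ann  <- generate_annotation(cfg)
chip <- generate_chipseq_pair(cfg, ann)

dha <- compute_dha(chip$peaks_control, chip$peaks_uv, ann)
table(dha$dha_class)
#> down none   up
#>   30  140   30

m <- merged_region_signal(chip$peaks_control, chip$peaks_uv)
global_signal_slope(m$tags_a, m$tags_b)
#> [1] 0.5324
```

The 30/30 up/down genes are exactly the planted ±4-fold acetylation
effects (the remaining 140 genes stay unclassified), and the slope below
1 reflects the generator's global 0.7× UV scaling compounded by the
planted losses — a net genome-wide H3K27ac loss.

```r
se_c <- call_superenhancers(chip$peaks_control, ann, sample = "control")
se_u <- call_superenhancers(chip$peaks_uv, ann, sample = "uv")
se_c; se_u
#> se_set [control]: 22 SEs of 522 stitched enhancers (cutoff signal 77.49)
#> se_set [uv]: 19 SEs of 522 stitched enhancers (cutoff signal 54.24)
```

22 control SEs (20 planted clusters plus two boosted-background
enhancers above the transition point) against 19 after UV: the planted
loss of 5 clusters and gain of 2 shows up as a net loss of 3.

```r
ex  <- generate_expression_pair(cfg, ann, chip$truth)
rec <- integrate_omics(compute_dge(ex$expression), dha)
group_shift_test(rec)
#>   group  n n_mid mean_shift        t  df            p testable
#> 1   gt1 30   140       1.90     6.20 168 4.27e-09     TRUE
#> 2  lt-1 30   140      -1.88    -6.12 168 6.48e-09     TRUE
```

Genes whose acetylation rose more than two-fold sit ~1.9 log2 units
higher in expression change than acetylation-stable genes (and
symmetrically for losses) — the planted acetylation–expression coupling,
recovered at p < 1e-8.

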