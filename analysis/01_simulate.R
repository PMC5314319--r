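#!/usr/bin/env Rscript
# Generate the synthetic UV study: a small genome annotation, paired
# control/UV H3K27ac peak landscapes with planted super-enhancer clusters
# and differential-acetylation genes, a paired expression table with
# acetylation-coupled planted effects, two somatic SNV sets sharing a
# fixed common subset, and an shRNA depletion screen with planted
# skin-essential genes. Everything is seeded; the planted ground truth is
# written alongside the data.

library(uvomics)

seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L
cfg <- simulation_config(
  seed = seed,
  # study conditions for the variant arm: 463 and 417 SNVs at the two
  # timepoints, 75 shared, with a fixed per-category composition for the
  # shared set
  n_variants_a = 463, n_variants_b = 417, n_variants_common = 75,
  common_category_counts = c(intron = 26, exon = 15, utr5 = 9, utr3 = 2,
                             upstream1kb = 2, intergenic = 21))
sim <- simulate_uv_study(cfg, "results/simulated")

cat("Simulated study written to results/simulated (seed ", seed, "):\n",
    "  ", length(sim$annotation$genes), " genes on ",
    length(cfg$chrom_lengths), " chromosomes\n",
    "  ", length(sim$chipseq$peaks_control), " H3K27ac peaks per sample, ",
    cfg$n_planted_se_clusters, " planted SE clusters\n",
    "  ", nrow(sim$variants$variants_a), " / ",
    nrow(sim$variants$variants_b), " SNVs (",
    cfg$n_variants_common, " common)\n",
    "  screen: ", nrow(sim$screen$screen$ds), " shRNAs x ",
    ncol(sim$screen$screen$ds), " cell lines, ",
    length(sim$screen$truth$essential), " planted essential genes\n",
    sep = "")
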