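#!/usr/bin/env Rscript
# Achilles-style gene essentiality from the shRNA depletion screen:
# negative-control centering per sample, within-gene consistency filter
# (the gene's shRNA pairwise score differences must rank below random
# shRNA pairs, p < 0.1), gene-level median collapse, and a one-sided
# rank-sum test for lower depletion scores in skin than non-skin lines
# (p < 0.05 flags a skin-specific essential gene).

library(uvomics)

seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L
dsdf <- read.delim("results/simulated/screen_ds.tsv", check.names = FALSE)
ds <- as.matrix(dsdf[, -1]); rownames(ds) <- dsdf[[1]]
map <- read.delim("results/simulated/screen_map.tsv")
lin <- read.delim("results/simulated/screen_lineage.tsv")
gene <- map$gene[match(rownames(ds), map$shrna)]
gene[!nzchar(gene) | is.na(gene)] <- NA
scr <- screen_matrix(ds, gene,
                     map$is_negative_control[match(rownames(ds), map$shrna)],
                     lin$lineage[match(colnames(ds), lin$line)])

res <- run_essentiality_pipeline(scr, seed = seed)
write.table(res, "results/essentiality.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(nrow(res), "genes tested;", sum(res$consistency_pass),
    "with consistent shRNAs;", sum(res$skin_specific, na.rm = TRUE),
    "flagged skin-specific essential\n")
truth <- jsonlite::read_json("results/simulated/truth.json")
planted <- unlist(truth$screen$essential)
hits <- res$gene_id[which(res$skin_specific)]
cat(sprintf("Planted recovery: %d/%d (false positives: %d)\n",
            sum(planted %in% hits), length(planted),
            sum(!hits %in% planted)))
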