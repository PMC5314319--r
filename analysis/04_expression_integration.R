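#!/usr/bin/env Rscript
# Differential expression and its integration with differential
# acetylation. Genes are binned by acetylation log2FC (> 1, < -1, middle)
# and the expression log2FC of each extreme bin is compared to the middle
# bin by Student's t-test; the 3x3 class-by-class concordance matrix
# summarises co-directional (positive) and opposed (inverse) regulation.

library(uvomics)

ann <- read_gene_annotation("results/simulated/genes.gff3")
expr <- read.delim("results/simulated/expression.tsv")
dge <- compute_dge(expr, fc_cutoff = 2)
dha <- read.delim("results/dha.tsv")

rec <- integrate_omics(dge, dha)
write.table(rec, "results/integration.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(dge, "results/dge.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("DGE genes:", sum(dge$dge_class != "none"), "of", nrow(dge), "\n")
gs <- group_shift_test(rec)
print(gs)
cat("Concordance matrix (rows expression, cols acetylation):\n")
print(concordance_matrix(rec))
pos <- sum(rec$concordance == "positive")
inv <- sum(rec$concordance == "inverse")
cat(pos, "positively and", inv, "inversely correlated genes;",
    nrow(rec) - pos - inv, "discordant or unresponsive\n")
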